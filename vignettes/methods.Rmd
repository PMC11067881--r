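---
title: "Methods: orthogroup specificity, family dynamics, macrosynteny and marker profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orthogroup specificity, family dynamics, macrosynteny and marker profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoclades)
```

This vignette documents the models, conventions and design choices behind
the package, in the order the pipeline runs them.

## Data model and conventions

An orthogroup table maps each orthogroup to per-species gene-identifier
lists (the OrthoFinder `Orthogroups.tsv` dialect); an empty cell is legal
and means "absent in this species". Gene identifiers are matched between
files by exact string equality after whitespace trimming — no fuzzy
matching, because silent mismatches are worse than errors. The proteomes
such tables are built from are normally splice-filtered (one entry per
gene), so no isoform stripping is applied by default.

Genomic intervals are stored 0-based half-open internally; GFF3 I/O
(1-based closed) converts at the boundary and nowhere else, which keeps all
interval arithmetic uniform and makes export–import an involution. Species
trees are `ape` `phylo` objects; internal nodes without labels receive
stable identifiers `N1..Nk`, and all node references elsewhere in the
package are by label.

## Taxon-specificity classification

For orthogroup $O$ with possessor set $P(O)$ (species with at least one
gene), $O$ is *confined to clade $X$* iff $P(O) \subseteq \mathrm{leaves}(X)$.
Confinement is deliberately inclusive rather than MRCA-exclusive: a
genus-confined orthogroup is also confined to every enclosing clade, so
counts are monotone along a nested ladder. This is the only reading under
which a published ladder of clade-specific percentages can decrease
monotonically with clade size, and the MRCA column in the output provides
the exclusive (phylostratigraphic) stratification for anyone who wants it.
Presence requires one gene — no minimum-species floor is imposed for
confinement — while "species-specific" requires exactly one possessor
species regardless of gene count.

The five-way proteome partition assigns each focal-species gene the first
matching rule: single-possessor orthogroup → species-specific; orthogroup
confined to the focal phylum → phylum-specific (genus, family and subphylum
levels merged by design); confined to Metazoa → metazoan-specific;
otherwise → other-multispecies (the residual bucket, which guarantees the
partition is total); genes in no orthogroup → unassigned. Unassigned genes
stay in the denominator, mirroring how proteome-composition figures include
an unassigned wedge.

Exclusive overlaps between named disjoint species groups count, for every
nonempty group combination, the orthogroups possessed in every group of the
combination and in none outside it; orthogroups possessed only by
un-grouped species drop out of the universe, so combination counts always
sum to the number of orthogroups with at least one partitioned possessor.

## Gene-family dynamics

When the family-count table carries internal-node columns (for example
CAFE ancestral states) they are used verbatim and the output is flagged
`provenance = "external"`. Otherwise ancestral counts are filled by
linear-cost (Wagner) parsimony: a Sankoff dynamic program over states
$0..max$, cost $|parent - child|$ per branch, with the min-convolution
computed in $O(S)$ per node by forward/backward passes. Ties are broken by
the smallest count at each node, resolved root to tip, which makes the
reconstruction deterministic; this is a documented divergence from
probabilistic birth–death ancestral states, whose likelihoods this package
does not attempt to reproduce. The tests verify the program against
exhaustive enumeration on all trees up to 6 leaves and states up to 6.

Per branch (identified by its child node), the per-family delta
$n(\mathrm{child}) - n(\mathrm{parent})$ is tallied into families
expanded/contracted/unchanged and gene copies gained/lost. The
terminal-vs-internal comparison is a two-sided Welch two-sample t-test; the
default metric is the per-branch number of families changed (expanded +
contracted), chosen because branch-level change counts of that magnitude
are what such comparisons report; the gene-copy metric is available by
argument. The two-species report compares each terminal branch against a
reference ancestor: the fraction of families changed uses as denominator
the families with nonzero count at that leaf ("present in the genome"),
and "lost" means nonzero at the reference node but zero at the leaf; the
gain ratio is first/second species, the loss ratio second/first.

## Macrosynteny

Shared-orthogroup counts collapse orthogroups to presence per scaffold, so
multi-copy genes cannot inflate a pair. Orthogroups placed on more than 5
scaffolds in either species (configurable) are excluded as promiscuous —
a guard against repeat-derived families dominating the matrix. The
enrichment test for scaffold pair $(a, b)$ is the exact hypergeometric
upper tail $P(X \ge k)$ with $K$ and $n$ the scaffolds' distinct-orthogroup
margins and $N$ the shared universe, BH-corrected at FDR 0.05 across all
pairs with $k \ge 1$. BH was chosen as the field-standard FDR control for
enrichment screens; the specific clustering statistic behind published
scaffold-clustering figures is rarely stated, so this realization is
declared as a reconstruction. Linkage groups are connected components of
the significant-pair graph: deterministic and parameter-free, at the known
cost of chaining risk on fragmented assemblies (a community-detection step
would add a resolution parameter without removing that risk). Dot-plot
axes order scaffolds by linkage group, then gene count descending, then
scaffold id, and genes by start coordinate — fully deterministic.

## Marker evolutionary profiling

The default strict filter is adjusted $p \le 0.05$, average
$\log_2\mathrm{FC} \ge 0.25$, detection in $\ge 25\%$ of cluster cells,
positive markers only — the Seurat marker-calling conventions commonly
used for hydrozoan cell atlases; every threshold is exposed because
published "strict criteria" often live in supplements. Each filtered
marker is annotated with `not_assigned`, `species_specific`, the smallest
ladder clade its orthogroup is confined to, or `other_multispecies`; the
ladder itself is an argument (the analysis scripts use genus →
genus+Clytia → Hydrozoa → Medusozoa → Cnidaria → Metazoa, a reconstruction
of the usual eight-bucket legend). The lineage-specific fraction counts
species-specific plus all ladder categories below the metazoan level; its
denominator includes not-assigned markers by default (they are
evolutionarily uncharacterized, not known-shared), with an
`assigned_only` switch reporting the alternative since either convention
appears in practice. A gene marking several clusters counts once per
cluster in per-cluster profiles but once only in pooled groups such as the
i-cell sharing histogram.

## Synthetic data

The generator emulates the statistical structure the analyses assume, not
sequence evolution. Families originate on a uniformly drawn branch (root
included) with one copy; below the origin each branch applies an
irreversible Dollo loss with probability 0.05 (default) or a $\pm 1$
copy-number step with probability 0.3; zero is absorbing, so drift cannot
resurrect a lost family — chosen because confinement classification
assumes single origin. Genome pairs place every orthogroup into one of 5
ancestral linkage groups split over 2 scaffolds per group per species,
with 2% per-gene translocation and 10% per-scaffold window inversions as
defaults — enough noise to be visible, little enough that planted groups
remain recoverable. Marker tables draw genes from category strata at
planted per-cluster proportions and draw the numeric fields so planted
pass/fail labels are realized exactly under the default filter. All
randomness flows from one integer seed through named substreams (fixed
offsets per stage), so outputs are byte-identical across runs and adding a
stage never perturbs earlier draws.

What passing tests show — and what they do not: the simulator produces
single-origin presence/absence patterns, independent per-branch events and
uniform origination. Real orthogroup tables additionally contain
inference artifacts (split/merged orthogroups, contamination, annotation
gaps) and strongly non-uniform origination; planted-truth recovery here
therefore validates the *bookkeeping*, not robustness to those artifacts.

## Problem sizes and numerical choices

The analysis scripts and the acceptance script simulate 5000 families on a
22-leaf study-shaped tree (15 cnidarians, 4 bilaterians, 3 outgroups),
5 linkage groups and 3 marker clusters of up to 300 markers — sizes at
which every stage's behaviour is clearly resolved while a full run stays
in seconds. Property tests use 4–8-leaf trees where exhaustive enumeration
is the oracle. Proportion vectors are checked to sum to 1 within 1e-9;
hypergeometric tails match direct mass summation within 1e-12; Welch
results match the closed form within 1e-10. Degenerate inputs are defined
rather than accidental: empty filter results warn, zero significant
scaffold pairs yield singleton groups with a warning, an empty overlap
universe is a hard error.

## Known limitations

Confinement ignores branch lengths and cannot distinguish loss from
incomplete sampling; the parsimony fallback understates changes relative
to birth–death models when rates are high; connected-component linkage
groups can chain through a single spurious pair on fragmented assemblies;
and the marker stage inherits whatever biases the upstream clustering and
marker calling introduced.
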