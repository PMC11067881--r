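# orthoclades

Downstream comparative-genomic analyses for cnidarian (and other) genome
projects that start from an OrthoFinder-style orthogroup table and a rooted
species tree. The package targets the questions a genome paper's
"evolutionary novelty" sections ask:

- **Taxon specificity.** For each orthogroup O with possessor set
  P(O) (species with ≥ 1 gene), O is *confined to clade X* iff
  P(O) ⊆ leaves(X). Confinement is inclusive, so counts are nested along a
  ladder such as Cnidaria ⊇ Medusozoa ⊇ Hydrozoa ⊇ genus; the MRCA node of
  P(O) gives the complementary exclusive (phylostratigraphic) view.
- **Proteome partition.** Every gene of a focal species falls in exactly one
  of five buckets: species-specific, phylum-specific (genus/family/subphylum
  merged), metazoan-specific, other-multispecies, unassigned.
- **Gene-family dynamics.** Given per-family counts at the leaves (and
  optionally at internal nodes, e.g. from CAFE), missing ancestral counts are
  filled by linear-cost (Wagner/Sankoff) parsimony minimising
  Σ_branches |n(child) − n(parent)|. Per-branch expansions/contractions are
  tallied and terminal vs internal branches compared with a two-sided Welch
  t-test on the per-branch number of families changed.
- **Macrosynteny.** For a genome pair, scaffold pairs are scored by shared
  orthogroup presence; the upper-tail hypergeometric p-value
  P(X ≥ k), X ~ Hypergeom(N, K, n) with BH correction defines significant
  pairs, whose connected components are putative linkage groups
  (Oxford-style dot-plot coordinates included).
- **Marker evolutionary profiling.** Seurat-style cluster markers are
  strictly filtered, annotated with the smallest ladder clade their
  orthogroup is confined to, and summarised per cluster/cell type as
  category profiles and lineage-specific fractions, plus a sharing
  histogram for stem-cell (i-cell) clusters.

A synthetic-data generator (families originating on branches with Dollo
losses and copy-number drift; genomes descending from shared ancestral
linkage groups; marker tables with planted mixtures) provides ground truth
so every stage is tested without downloads.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (seed 1): `01_simulate.R` writes the inputs under `results/data/`,
then

```sh
Rscript analysis/02_specificity.R
```

prints

```
confinement ladder (fraction of orthogroups):
  Cnidaria             67.9%
  Medusozoa            49.3%
  Hydrozoa             34.8%
  Hydractinia_Clytia   16.1%
  Hydractinia          6.9%
highest phylum-specific proportion: Hydractinia_echinata at 73.3%
```

— the nested confinement ladder over the 4899 surviving simulated families
and the cnidarian species with the largest phylum-specific gene share.
`analysis/03_family_dynamics.R` then reports

```
Welch t-test (families_changed): mean[terminal] = 233.3, mean[internal] = 122,
  t = 8.5833, df = 33.95, p = 5.06e-10
```

meaning terminal branches accumulate significantly more family-size changes
than internal ones under the simulated drift process, and the two
*Hydractinia* terminal branches lose non-overlapping family sets
(lost-set overlap = 0). `04_macrosynteny.R` recovers the 5 planted linkage
groups from 20 significant scaffold pairs; `05_markers.R` profiles the
filtered markers per cluster.

Equivalent one-call orchestration:

```r
library(orthoclades)
report <- run_pipeline(run_config(seed = 1, out_dir = "results/run"))
```

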