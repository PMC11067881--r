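#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Simulates 5000 gene families on the 22-leaf study-shaped tree (families
# originate on uniformly drawn branches, suffer irreversible Dollo losses at
# 0.05 per branch and +/-1 copy-number drift at 0.3 per branch), a genome
# pair for the two Hydractinia leaves descending from 5 shared ancestral
# linkage groups (2% translocation, 10% inversion), and a 3-cluster marker
# table with planted category mixtures. Everything is written in the
# external dialects the package reads back (Orthogroups.tsv, Newick +
# clade TSV, CAFE tab counts, GFF3, marker CSV), so stages 02-05 exercise
# the full I/O path.

suppressPackageStartupMessages(library(orthoclades))

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ex <- example_study_tree()
ape::write.tree(ex$tree, file.path(out, "species_tree.nwk"))
write_clade_config(ex$clades, file.path(out, "clades.tsv"))

content <- simulate_gene_content(ex$tree, n_families = 5000,
                                 loss_prob = 0.05, drift_prob = 0.3,
                                 seed = seed)
write_orthogroups(content$orthogroups, file.path(out, "Orthogroups.tsv"))
write_family_counts(content$counts, file.path(out, "family_counts.tsv"))
check_content_truth(content, ex$tree)

pair <- c("Hydractinia_symbiolongicarpus", "Hydractinia_echinata")
genomes <- simulate_genomes(content, pair, n_groups = 5,
                            translocation_rate = 0.02,
                            inversion_rate = 0.1, seed = seed)
for (sp in pair) {
  write_gene_positions(genomes$positions[[sp]],
                       file.path(out, paste0(sp, ".gff3")))
}

g2og <- gene_to_og_map(content$orthogroups)
assignment <- classify_orthogroups(content$orthogroups, ex$tree, ex$clades)
focal_genes <- names(g2og)[startsWith(names(g2og), paste0(pair[1], "|"))]
gc <- gene_categories(content$orthogroups, assignment, pair[1],
                      focal_genes, ex$clades)
strata <- stats::setNames(gc$genes$category, gc$genes$gene)
avail <- table(strata[strata != "unassigned"])
avail <- avail[avail >= 25]
w <- as.vector(avail) / sum(avail)
names(w) <- names(avail)
markers <- simulate_markers(strata, list(C1 = w, C2 = w, C3 = w),
                            n_per_cluster = min(300L, floor(sum(avail) / 3)),
                            fail_fraction = 0.2, seed = seed)
write_markers(markers$markers, file.path(out, "markers.csv"))
utils::write.table(markers$truth, file.path(out, "marker_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d surviving families (%d genes) over %d species\n",
            length(content$orthogroups$og_id),
            length(g2og), length(ex$tree$tip.label)))
cat(sprintf("genome pair: %d + %d placed genes; markers: %d rows\n",
            nrow(genomes$positions[[1]]), nrow(genomes$positions[[2]]),
            nrow(markers$markers)))
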