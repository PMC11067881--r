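#!/usr/bin/env Rscript
# Stage 5: evolutionary profile of single-cell cluster markers.
#
# Reads the simulated marker table, applies the strict filter (adjusted
# p <= 0.05, log2FC >= 0.25, expressed in >= 25% of cluster cells,
# positive only), annotates each surviving marker with the smallest clade
# its orthogroup is confined to, and reports per-cluster category profiles,
# lineage-specific fractions and the pooled sharing histogram.

suppressPackageStartupMessages(library(orthoclades))

data_dir <- "results/data"
og <- read_orthogroups(file.path(data_dir, "Orthogroups.tsv"))
tc <- read_tree_and_clades(file.path(data_dir, "species_tree.nwk"),
                           file.path(data_dir, "clades.tsv"))
markers <- read_markers(file.path(data_dir, "markers.csv"))

assignment <- classify_orthogroups(og, tc$tree, tc$clades)
kept <- filter_markers(markers, filter_criteria())
cat(sprintf("filter kept %d of %d markers\n", nrow(kept), nrow(markers)))

ladder <- c("Hydractinia", "Hydractinia_Clytia", "Hydrozoa", "Medusozoa",
            "Cnidaria", "Metazoa")
ann <- assign_marker_categories(kept, assignment, ladder,
                                gene_to_og_map(og))
grouping <- stats::setNames(unique(ann$cluster), unique(ann$cluster))
prof <- group_profiles(ann, grouping)
summ <- attr(prof, "summary")
utils::write.table(prof, "results/marker_profiles.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(summ, "results/marker_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("lineage-specific fraction per cluster:\n")
for (i in seq_len(nrow(summ))) {
  cat(sprintf("  %-4s %5.1f%%  (%d markers)\n", summ$group[i],
              100 * summ$lineage_specific_fraction[i], summ$n_markers[i]))
}

hist <- icell_sharing_histogram(ann, unique(ann$cluster), assignment,
                                min_shared = 15)
utils::write.table(
  data.frame(n_species = names(hist$histogram), n_markers = hist$histogram),
  "results/sharing_histogram.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
cat(sprintf("%d orthogroup-assigned markers; %.1f%% shared by >= 15 species\n",
            hist$n_assigned, 100 * hist$fraction_widely_shared))
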