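#!/usr/bin/env Rscript
# Stage 2: taxon specificity of every orthogroup.
#
# Reads the simulated orthogroup table and species tree, classifies every
# orthogroup's confinement along the clade ladder, partitions each cnidarian
# proteome into the five lineage-specificity categories, and tabulates the
# exclusive overlaps between Medusozoa, Anthozoa and Bilateria.

suppressPackageStartupMessages(library(orthoclades))

data_dir <- "results/data"
out <- "results"
og <- read_orthogroups(file.path(data_dir, "Orthogroups.tsv"))
tc <- read_tree_and_clades(file.path(data_dir, "species_tree.nwk"),
                           file.path(data_dir, "clades.tsv"))

assignment <- classify_orthogroups(og, tc$tree, tc$clades)
write_tsv <- function(df, name) {
  utils::write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
write_tsv(specificity_table(assignment), "specificity.tsv")

conf <- confinement_fractions(assignment)
cat("confinement ladder (fraction of orthogroups):\n")
for (cl in c("Cnidaria", "Medusozoa", "Hydrozoa", "Hydractinia_Clytia",
             "Hydractinia")) {
  cat(sprintf("  %-20s %.1f%%\n", cl, 100 * conf[[cl]]))
}

g2og <- gene_to_og_map(og)
rows <- lapply(intersect(tc$clades$sets$Cnidaria, og$species_order),
               function(sp) {
  genes <- names(g2og)[startsWith(names(g2og), paste0(sp, "|"))]
  if (length(genes) == 0) return(NULL)
  gc <- gene_categories(og, assignment, sp, genes, tc$clades)
  data.frame(species = sp, t(gc$proportions))
})
cats <- do.call(rbind, rows)
write_tsv(cats, "gene_categories.tsv")
best <- cats[which.max(cats$phylum_specific), ]
cat(sprintf("highest phylum-specific proportion: %s at %.1f%%\n",
            best$species, 100 * best$phylum_specific))

ov <- clade_overlaps(og, list(
  Medusozoa = tc$clades$sets$Medusozoa,
  Anthozoa = tc$clades$sets$Anthozoa,
  Bilateria = tc$clades$sets$Bilateria))
write_tsv(ov, "clade_overlaps.tsv")
cat("exclusive overlaps written for",
    sum(ov$n_orthogroups), "orthogroups\n")
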