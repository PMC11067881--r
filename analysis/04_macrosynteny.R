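#!/usr/bin/env Rscript
# Stage 4: macrosynteny of the simulated Hydractinia genome pair.
#
# Builds the scaffold x scaffold shared-orthogroup matrix, tests each pair
# for hypergeometric enrichment (BH at FDR 0.05), clusters scaffolds into
# linkage groups as connected components of the significant-pair graph, and
# writes dot-plot coordinates.

suppressPackageStartupMessages(library(orthoclades))

data_dir <- "results/data"
pair <- c("Hydractinia_symbiolongicarpus", "Hydractinia_echinata")
og <- read_orthogroups(file.path(data_dir, "Orthogroups.tsv"))
posA <- read_gene_positions(file.path(data_dir, paste0(pair[1], ".gff3")),
                            "gff3", species = pair[1])
posB <- read_gene_positions(file.path(data_dir, paste0(pair[2], ".gff3")),
                            "gff3", species = pair[2])

m <- shared_og_matrix(posA, posB, gene_to_og_map(og))
cat(sprintf("shared-orthogroup universe: %d orthogroups, %d x %d scaffolds\n",
            m$N, nrow(m$counts), ncol(m$counts)))
tests <- test_scaffold_pairs(m, fdr = 0.05)
lg <- linkage_groups(tests, m)

utils::write.table(tests, "results/pair_tests.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(lg$groups, "results/linkage_groups.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(lg$dotplot, "results/dotplot.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("%d of %d scaffold pairs significant; %d linkage groups\n",
            sum(tests$significant), nrow(tests), max(lg$groups$group)))
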