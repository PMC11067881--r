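# Taxon-specificity classification of orthogroups against a ladder of named
# clades, per-species gene-category partitions, exclusive clade overlaps and
# species-sharing spectra.
#
# "Confined to clade X" is inclusive: every possessor species lies inside
# X's leaf set. Confinement flags are therefore nested along the ladder —
# every hydrozoan-confined orthogroup is also medusozoan- and
# cnidarian-confined. An MRCA-stratified (exclusive) view is carried
# alongside via the `mrca` column.

#' Classify the taxon specificity of every orthogroup
#'
#' For each orthogroup: the possessor species set (>= 1 gene), species and
#' gene counts, the MRCA tree node spanning the possessors, and one logical
#' confinement flag per configured clade (possessors all inside the clade's
#' leaf set).
#'
#' @param table an [orthogroup_table()].
#' @param tree labelled rooted [ape::phylo] tree whose leaves cover every
#'   possessor species.
#' @param clades a [clade_map()].
#' @return object of class `specificity_assignment`: list with `table`
#'   (data.frame: og_id, n_species, n_genes, mrca), `confined` (logical
#'   matrix orthogroups x clades, ladder order), `possessors` (list of
#'   species vectors) and the `clades` map.
#' @export
classify_orthogroups <- function(table, tree, clades) {
  counts <- og_gene_counts(table)
  pres <- counts > 0
  possessed <- rowSums(pres) > 0
  if (!all(possessed)) {
    counts <- counts[possessed, , drop = FALSE]
    pres <- pres[possessed, , drop = FALSE]
  }
  sp <- colnames(pres)
  missing <- setdiff(sp[colSums(pres) > 0], tree$tip.label)
  if (length(missing) > 0) {
    stop("possessor species absent from tree: ",
         paste(missing, collapse = ", "))
  }
  possessors <- apply(pres, 1, function(r) sp[r], simplify = FALSE)
  mrca <- vapply(possessors, function(p) mrca_label(tree, p), character(1))
  confined <- vapply(names(clades$sets), function(cl) {
    outside <- setdiff(sp, clades$sets[[cl]])
    rowSums(pres[, outside, drop = FALSE]) == 0
  }, logical(nrow(pres)))
  confined <- matrix(confined, nrow = nrow(pres),
                     dimnames = list(rownames(pres), names(clades$sets)))
  structure(
    list(
      table = data.frame(
        og_id = rownames(pres),
        n_species = as.integer(rowSums(pres)),
        n_genes = as.integer(rowSums(counts)),
        mrca = mrca,
        stringsAsFactors = FALSE
      ),
      confined = confined,
      possessors = possessors,
      clades = clades
    ),
    class = "specificity_assignment"
  )
}

#' @export
print.specificity_assignment <- function(x, ...) {
  cat("specificity_assignment:", nrow(x$table), "orthogroups\n")
  for (cl in colnames(x$confined)) {
    cat(sprintf("  confined to %-20s %6d (%.1f%%)\n", cl,
                sum(x$confined[, cl]),
                100 * mean(x$confined[, cl])))
  }
  invisible(x)
}

#' Fraction of orthogroups confined to each clade
#'
#' @param assignment a `specificity_assignment`.
#' @return named numeric vector of fractions over all assigned orthogroups.
#' @export
confinement_fractions <- function(assignment) {
  colMeans(assignment$confined)
}

# categories of the five-way proteome partition
gene_category_levels <- c("species_specific", "phylum_specific",
                          "metazoan_specific", "other_multispecies",
                          "unassigned")

#' Partition a focal species' genes into lineage-specificity categories
#'
#' Each gene of the focal species falls in exactly one of five buckets:
#' `species_specific` (its orthogroup has a single possessor species),
#' `phylum_specific` (orthogroup confined to the focal phylum clade;
#' genus/family/subphylum levels are deliberately merged here),
#' `metazoan_specific` (confined to the metazoan clade but not the phylum),
#' `other_multispecies` (the residual: possessed outside Metazoa), and
#' `unassigned` (gene in no orthogroup). Proportions are over `all_genes`,
#' so the unassigned wedge stays in the denominator.
#'
#' @param table an [orthogroup_table()].
#' @param assignment result of [classify_orthogroups()].
#' @param focal_species species name.
#' @param all_genes full gene list of the focal species (superset of its
#'   genes in `table`).
#' @param clades a [clade_map()] with one clade flagged `focal_phylum` and
#'   one flagged `metazoa`.
#' @return list with `genes` (data.frame gene, category) and `proportions`
#'   (named numeric of length 5, summing to 1).
#' @export
gene_categories <- function(table, assignment, focal_species, all_genes,
                            clades = assignment$clades) {
  phylum <- clade_with_role(clades, "focal_phylum")
  metazoa <- clade_with_role(clades, "metazoa")
  if (is.null(phylum) || is.null(metazoa)) {
    stop("clade map must flag a focal_phylum clade and a metazoa clade")
  }
  g2og <- gene_to_og_map(table)
  focal_in_table <- unlist(
    lapply(table$membership, function(mm) mm[[focal_species]]),
    use.names = FALSE
  )
  if (!all(focal_in_table %in% all_genes)) {
    stop("all_genes must cover every focal-species gene in the table")
  }
  og_cat <- function(og) {
    i <- match(og, assignment$table$og_id)
    if (is.na(i)) stop("orthogroup not in assignment: ", og)
    if (assignment$table$n_species[i] == 1) return("species_specific")
    if (assignment$confined[i, phylum]) return("phylum_specific")
    if (assignment$confined[i, metazoa]) return("metazoan_specific")
    "other_multispecies"
  }
  ogs <- unname(g2og[all_genes])
  cat_by_og <- vapply(unique(ogs[!is.na(ogs)]), og_cat, character(1))
  category <- ifelse(is.na(ogs), "unassigned", cat_by_og[ogs])
  props <- vapply(gene_category_levels,
                  function(l) mean(category == l), numeric(1))
  list(
    genes = data.frame(gene = all_genes, category = unname(category),
                       stringsAsFactors = FALSE),
    proportions = props
  )
}

#' Exclusive orthogroup overlaps between named species groups
#'
#' For a partition of (some) species into named, pairwise-disjoint groups,
#' counts for every nonempty group combination the orthogroups possessed by
#' at least one species of every group in the combination and by no species
#' of any group outside it. Species in no group are ignored for membership;
#' orthogroups possessed only by such species drop out of the universe.
#'
#' @param table an [orthogroup_table()].
#' @param groups named list of character vectors (group -> species).
#' @return data.frame with columns `combination` (group names joined by
#'   `"+"`, in `names(groups)` order) and `n_orthogroups`.
#' @export
clade_overlaps <- function(table, groups) {
  gn <- names(groups)
  if (is.null(gn) || anyDuplicated(gn)) stop("groups must be uniquely named")
  for (i in seq_along(groups)) {
    for (j in seq_len(i - 1L)) {
      if (length(intersect(groups[[i]], groups[[j]])) > 0) {
        stop("groups '", gn[j], "' and '", gn[i], "' overlap")
      }
    }
  }
  pres <- og_gene_counts(table) > 0
  memb <- vapply(groups, function(g) {
    rowSums(pres[, intersect(colnames(pres), g), drop = FALSE]) > 0
  }, logical(nrow(pres)))
  memb <- matrix(memb, nrow = nrow(pres), dimnames = list(NULL, gn))
  combo <- apply(memb, 1, function(r) paste(gn[r], collapse = "+"))
  keep <- combo != ""
  tab <- table(combo[keep])
  data.frame(combination = names(tab),
             n_orthogroups = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Species-sharing spectrum of a set of orthogroups
#'
#' Histogram of possessor-species counts over a subset of assigned
#' orthogroups.
#'
#' @param assignment a `specificity_assignment`.
#' @param subset character vector of orthogroup ids.
#' @return named integer vector: number of possessor species -> orthogroup
#'   count; values sum to `length(subset)`.
#' @export
sharing_spectrum <- function(assignment, subset) {
  subset <- as.character(subset)
  i <- match(subset, assignment$table$og_id)
  if (anyNA(i)) {
    stop("unknown orthogroup id(s): ",
         paste(subset[is.na(i)], collapse = ", "))
  }
  if (length(i) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(assignment$table$n_species[i])
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-orthogroup specificity table for export
#'
#' @param assignment a `specificity_assignment`.
#' @return data.frame: og_id, n_species, n_genes, mrca, plus one
#'   `confined_<clade>` logical column per clade.
#' @export
specificity_table <- function(assignment) {
  flags <- as.data.frame(assignment$confined)
  names(flags) <- paste0("confined_", colnames(assignment$confined))
  cbind(assignment$table, flags, row.names = NULL)
}
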