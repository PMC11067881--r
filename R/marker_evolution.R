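# Evolutionary profiling of single-cell cluster markers: strict filtering,
# annotation of every marker with the smallest clade its orthogroup is
# confined to, per-group category profiles, and the sharing histogram for
# stem-cell (i-cell) clusters.

#' Marker filtering criteria
#'
#' Defaults mirror the Seurat marker-calling conventions commonly used for
#' hydrozoan cell atlases: adjusted p <= 0.05, average log2 fold change
#' >= 0.25, expressed in >= 25% of cells in the cluster, positive markers
#' only. `max_pct_out` defaults to 1 (no ceiling).
#'
#' @param max_p_adj,min_log2fc,min_pct_in,max_pct_out numeric thresholds.
#' @param positive_only drop markers with negative fold change.
#' @return list of class `filter_criteria`.
#' @export
filter_criteria <- function(max_p_adj = 0.05, min_log2fc = 0.25,
                            min_pct_in = 0.25, max_pct_out = 1,
                            positive_only = TRUE) {
  stopifnot(is.finite(max_p_adj), max_p_adj >= 0, max_p_adj <= 1,
            is.finite(min_log2fc), is.finite(min_pct_in),
            is.finite(max_pct_out))
  structure(list(max_p_adj = max_p_adj, min_log2fc = min_log2fc,
                 min_pct_in = min_pct_in, max_pct_out = max_pct_out,
                 positive_only = positive_only),
            class = "filter_criteria")
}

#' Filter a marker table
#'
#' Keeps rows satisfying every criterion; reports kept/dropped counts per
#' cluster and warns (not errors) on an empty result.
#'
#' @param markers a `marker_table` data.frame (see [read_markers()]).
#' @param criteria a [filter_criteria()].
#' @return the filtered `marker_table`, with a `per_cluster` attribute
#'   (data.frame cluster, kept, dropped).
#' @export
filter_markers <- function(markers, criteria = filter_criteria()) {
  keep <- markers$p_val_adj <= criteria$max_p_adj &
    markers$avg_log2FC >= criteria$min_log2fc &
    markers$pct_in >= criteria$min_pct_in &
    markers$pct_out <= criteria$max_pct_out
  if (criteria$positive_only) keep <- keep & markers$avg_log2FC > 0
  per_cluster <- stats::aggregate(
    keep, by = list(cluster = markers$cluster),
    FUN = function(k) c(kept = sum(k), dropped = sum(!k))
  )
  per_cluster <- data.frame(cluster = per_cluster$cluster,
                            kept = per_cluster$x[, "kept"],
                            dropped = per_cluster$x[, "dropped"],
                            stringsAsFactors = FALSE)
  out <- markers[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("no markers pass the filter criteria")
  attr(out, "per_cluster") <- per_cluster
  out
}

#' Annotate filtered markers with their lineage-specificity category
#'
#' Category ladder (mutually exclusive, jointly exhaustive):
#' `not_assigned` (gene in no orthogroup), `species_specific` (orthogroup
#' with a single possessor species), then the smallest clade of `ladder`
#' to which the orthogroup is confined, and finally `other_multispecies`
#' (confined to no ladder clade).
#'
#' @param markers a (typically filtered) `marker_table`.
#' @param assignment a `specificity_assignment` (see
#'   [classify_orthogroups()]).
#' @param ladder character vector of clade names, ordered least to most
#'   inclusive; all must exist in the assignment's clade map.
#' @param gene_to_og named character vector gene -> orthogroup id (see
#'   [gene_to_og_map()]).
#' @return data.frame of class `annotated_markers`: the marker rows plus
#'   `og_id`, `category` (factor over the full ladder) and
#'   `n_possessor_species`.
#' @export
assign_marker_categories <- function(markers, assignment, ladder,
                                     gene_to_og) {
  bad <- setdiff(ladder, colnames(assignment$confined))
  if (length(bad) > 0) {
    stop("ladder clade(s) not in the clade map: ", paste(bad, collapse = ", "))
  }
  sizes <- lengths(assignment$clades$sets[ladder])
  if (is.unsorted(sizes)) {
    stop("ladder must be ordered least to most inclusive")
  }
  levels <- c("not_assigned", "species_specific", ladder,
              "other_multispecies")
  ogs <- unname(gene_to_og[markers$gene])
  known <- !is.na(ogs)
  i <- match(ogs[known], assignment$table$og_id)
  if (anyNA(i)) {
    stop("marker gene mapped to unknown orthogroup id: ",
         paste(unique(ogs[known][is.na(i)]), collapse = ", "))
  }
  category <- rep("not_assigned", nrow(markers))
  n_sp <- rep(NA_integer_, nrow(markers))
  n_sp[known] <- assignment$table$n_species[i]
  smallest <- function(row) {
    hit <- ladder[assignment$confined[row, ladder]]
    if (length(hit) == 0) "other_multispecies" else hit[1]
  }
  cat_known <- ifelse(assignment$table$n_species[i] == 1,
                      "species_specific",
                      vapply(i, smallest, character(1)))
  category[known] <- cat_known
  out <- markers
  out$og_id <- ogs
  out$category <- factor(category, levels = levels)
  out$n_possessor_species <- n_sp
  class(out) <- c("annotated_markers", "data.frame")
  out
}

#' Per-group evolutionary profiles of annotated markers
#'
#' Aggregates annotated markers into groups (a cluster-to-group mapping;
#' identity for per-cluster profiles) and reports per group the marker
#' count, the proportion vector over the category ladder, and the
#' lineage-specific fraction. The default denominator is all markers of
#' the group including `not_assigned`; set `denominator = "assigned_only"`
#' for the alternative.
#'
#' @param annotated an `annotated_markers` data.frame.
#' @param grouping named character vector cluster id -> group name; every
#'   cluster present in `annotated` must be mapped.
#' @param lineage_def categories counted as lineage-specific; default is
#'   everything from species-specific up to (and including) the most
#'   inclusive ladder clade below the metazoan level, i.e. all ladder
#'   categories except the last, plus `species_specific`.
#' @param denominator `"all"` or `"assigned_only"`.
#' @return data.frame: one row per (group, category) with `n` and
#'   `proportion`, plus attribute `summary` (data.frame group, n_markers,
#'   lineage_specific_fraction).
#' @export
group_profiles <- function(annotated, grouping,
                           lineage_def = NULL,
                           denominator = c("all", "assigned_only")) {
  denominator <- match.arg(denominator)
  unmapped <- setdiff(unique(annotated$cluster), names(grouping))
  if (length(unmapped) > 0) {
    stop("cluster(s) missing from grouping: ",
         paste(unmapped, collapse = ", "))
  }
  levels <- levels(annotated$category)
  if (is.null(lineage_def)) {
    ladder <- setdiff(levels, c("not_assigned", "species_specific",
                                "other_multispecies"))
    lineage_def <- c("species_specific", utils::head(ladder, -1))
  }
  group <- unname(grouping[annotated$cluster])
  counts <- table(group = group, category = annotated$category)
  long <- as.data.frame(counts, stringsAsFactors = FALSE)
  names(long) <- c("group", "category", "n")
  totals <- rowSums(counts)
  long$proportion <- ifelse(totals[long$group] > 0,
                            long$n / totals[long$group], 0)
  denom <- if (denominator == "all") totals else {
    totals - counts[, "not_assigned"]
  }
  lin <- rowSums(counts[, intersect(lineage_def, colnames(counts)),
                        drop = FALSE])
  summary <- data.frame(
    group = rownames(counts),
    n_markers = as.integer(totals),
    lineage_specific_fraction = ifelse(denom > 0, lin / denom, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(long, "summary") <- summary
  long
}

#' Sharing histogram for stem-cell cluster markers
#'
#' Restricts to markers of the named clusters that are orthogroup-assigned
#' (deduplicated by gene across clusters), and reports how many possessor
#' species share each marker's orthogroup, the assigned-marker count, and
#' the fraction shared by at least `min_shared` species.
#'
#' @param annotated an `annotated_markers` data.frame.
#' @param clusters nonempty character vector of cluster ids.
#' @param assignment the `specificity_assignment` used to annotate.
#' @param min_shared species threshold for the widely-shared fraction
#'   (default 40).
#' @return list: `histogram` (named integer vector n_species -> markers),
#'   `n_assigned`, `fraction_widely_shared`.
#' @export
icell_sharing_histogram <- function(annotated, clusters, assignment,
                                    min_shared = 40) {
  if (length(clusters) == 0) stop("clusters must be nonempty")
  unknown <- setdiff(clusters, unique(annotated$cluster))
  if (length(unknown) > 0) {
    stop("unknown cluster(s): ", paste(unknown, collapse = ", "))
  }
  rows <- annotated[annotated$cluster %in% clusters &
                      !is.na(annotated$og_id), , drop = FALSE]
  # a gene marking several of the pooled clusters counts once
  rows <- rows[!duplicated(rows$gene), , drop = FALSE]
  if (nrow(rows) == 0) {
    return(list(histogram = stats::setNames(integer(0), character(0)),
                n_assigned = 0L, fraction_widely_shared = NA_real_))
  }
  # per-marker counting: duplicated orthogroup ids are intentional
  hist <- sharing_spectrum(assignment, rows$og_id)
  list(
    histogram = hist,
    n_assigned = nrow(rows),
    fraction_widely_shared = mean(rows$n_possessor_species >= min_shared)
  )
}
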