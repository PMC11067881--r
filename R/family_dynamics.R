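# Per-branch gene-family size-change summaries. Ancestral counts come from
# the input table when it carries internal-node columns (e.g. CAFE output,
# provenance "external"); otherwise a linear-cost (Wagner/Sankoff) parsimony
# dynamic program fills them (provenance "parsimony"). Downstream: per-branch
# expansion/contraction tallies, the Welch terminal-vs-internal comparison,
# and two-species terminal-branch reports.

#' Infer ancestral family counts by linear-cost parsimony
#'
#' Per family, internal-node counts minimise the total absolute change
#' `sum |parent - child|` over all branches (Sankoff dynamic program over
#' states `0..max_count`). Ties are broken deterministically by taking the
#' smallest count at each node, resolved root to tip — a divergence from
#' probabilistic (birth-death) ancestral states, which this program does
#' not attempt to reproduce.
#'
#' @param leaf_counts `family_counts` matrix covering every leaf of `tree`
#'   (internal-node columns, if present, are ignored here).
#' @param tree labelled rooted [ape::phylo] tree with >= 2 leaves.
#' @param max_count state-space cap; defaults to the maximum leaf count.
#' @return `family_counts` matrix over all nodes (leaves unchanged), with
#'   attribute `provenance = "parsimony"`.
#' @export
infer_ancestral_counts <- function(leaf_counts, tree, max_count = NULL) {
  if (length(tree$tip.label) < 2) stop("tree must have at least 2 leaves")
  miss <- setdiff(tree$tip.label, colnames(leaf_counts))
  if (length(miss) > 0) {
    stop("leaf counts missing for: ", paste(miss, collapse = ", "))
  }
  leaves <- leaf_counts[, tree$tip.label, drop = FALSE]
  if (is.null(max_count)) max_count <- max(leaves)
  if (max_count < max(leaves)) stop("max_count below maximum leaf count")
  states <- 0:max_count
  S <- length(states)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")$edge
  labs <- all_node_labels(tree)
  root <- setdiff(post[, 1], post[, 2])[1]

  # min-convolution with linear cost: m(s) = min_t |s - t| + v(t), O(S)
  linear_min <- function(v) {
    if (S == 1) return(v)
    m <- v
    for (s in 2:S) m[s] <- min(m[s], m[s - 1] + 1)
    for (s in (S - 1):1) m[s] <- min(m[s], m[s + 1] + 1)
    m
  }

  out <- matrix(0L, nrow = nrow(leaves), ncol = nnode,
                dimnames = list(rownames(leaves), labs))
  out[, seq_len(ntip)] <- as.integer(leaves)
  children <- split(post[, 2], post[, 1])

  for (f in seq_len(nrow(leaves))) {
    cost <- matrix(Inf, nrow = nnode, ncol = S)
    for (t in seq_len(ntip)) cost[t, leaves[f, t] + 1L] <- 0
    for (node in unique(post[, 1])) {
      kids <- children[[as.character(node)]]
      acc <- numeric(S)
      for (k in kids) acc <- acc + linear_min(cost[k, ])
      cost[node, ] <- acc
    }
    # backtrace root to tip, smallest state among minimizers
    assign_state <- integer(nnode)
    assign_state[root] <- which.min(cost[root, ]) - 1L
    pre <- post[rev(seq_len(nrow(post))), , drop = FALSE]
    for (e in seq_len(nrow(pre))) {
      parent <- pre[e, 1]; child <- pre[e, 2]
      if (child <= ntip) next
      total <- abs(assign_state[parent] - states) + cost[child, ]
      assign_state[child] <- which.min(total) - 1L
    }
    out[f, (ntip + 1):nnode] <- assign_state[(ntip + 1):nnode]
  }
  structure(out, class = c("family_counts", class(unclass(out))),
            provenance = "parsimony")
}

#' Attach ancestral counts to a family count table
#'
#' Uses internal-node columns verbatim when the table has them (provenance
#' `"external"`); otherwise runs [infer_ancestral_counts()].
#'
#' @param counts a `family_counts` matrix (leaves always; internal nodes
#'   optional).
#' @param tree labelled rooted [ape::phylo] tree.
#' @return complete `family_counts` matrix with a `provenance` attribute.
#' @export
ancestral_counts <- function(counts, tree) {
  labs <- all_node_labels(tree)
  if (all(labs %in% colnames(counts))) {
    out <- counts[, labs, drop = FALSE]
    attr(out, "provenance") <- "external"
    return(out)
  }
  infer_ancestral_counts(counts, tree)
}

#' Per-branch family expansion/contraction tallies
#'
#' For each branch (identified by its child node), per-family delta =
#' child count - parent count; tallies families expanded / contracted /
#' unchanged and gene copies gained (sum of positive deltas) and lost
#' (sum of absolute negative deltas). The root has no branch row.
#'
#' @param counts complete `family_counts` matrix (all nodes).
#' @param tree labelled rooted [ape::phylo] tree.
#' @return data.frame of class `branch_changes`: child, parent, terminal,
#'   n_families_expanded, n_families_contracted, n_families_unchanged,
#'   genes_gained, genes_lost.
#' @export
branch_changes <- function(counts, tree) {
  bt <- branch_table(tree)
  miss <- setdiff(unique(c(bt$child, bt$parent)), colnames(counts))
  if (length(miss) > 0) {
    stop("missing node count(s): ", paste(miss, collapse = ", "))
  }
  res <- lapply(seq_len(nrow(bt)), function(e) {
    d <- counts[, bt$child[e]] - counts[, bt$parent[e]]
    data.frame(
      child = bt$child[e], parent = bt$parent[e], terminal = bt$terminal[e],
      n_families_expanded = sum(d > 0),
      n_families_contracted = sum(d < 0),
      n_families_unchanged = sum(d == 0),
      genes_gained = sum(d[d > 0]),
      genes_lost = sum(-d[d < 0]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  class(out) <- c("branch_changes", "data.frame")
  out
}

#' Welch test: do terminal branches change more than internal ones?
#'
#' Two-sided Welch two-sample t-test on a per-branch change metric,
#' comparing branches ending in a leaf against internal branches. The
#' default metric is the number of families changed
#' (expanded + contracted) per branch; `"genes_changed"` uses gene copies
#' (gained + lost).
#'
#' @param bct a `branch_changes` data.frame.
#' @param metric `"families_changed"` or `"genes_changed"`.
#' @return list of class `welch_result`: mean_terminal, mean_internal,
#'   t, df (Welch-Satterthwaite, real-valued), p.
#' @export
terminal_vs_internal_test <- function(bct,
                                      metric = c("families_changed",
                                                 "genes_changed")) {
  metric <- match.arg(metric)
  x <- if (metric == "families_changed") {
    bct$n_families_expanded + bct$n_families_contracted
  } else {
    bct$genes_gained + bct$genes_lost
  }
  term <- x[bct$terminal]
  int <- x[!bct$terminal]
  if (length(term) < 2 || length(int) < 2) {
    stop("need >= 2 branches in each class (terminal: ", length(term),
         ", internal: ", length(int), ")")
  }
  tt <- stats::t.test(term, int, var.equal = FALSE)
  structure(
    list(mean_terminal = mean(term), mean_internal = mean(int),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, metric = metric),
    class = "welch_result"
  )
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf(
    "Welch t-test (%s): mean[terminal] = %.4g, mean[internal] = %.4g,\n  t = %.4f, df = %.2f, p = %.3g\n",
    x$metric, x$mean_terminal, x$mean_internal, x$t, x$df, x$p))
  invisible(x)
}

#' Compare two species' terminal-branch family dynamics
#'
#' For a species pair and a reference ancestor node: per species, the
#' fraction of families (nonzero at the leaf) whose size differs from the
#' reference-node size; gene copies gained and lost on the terminal branch;
#' the cross-species gain ratio (first / second) and loss ratio
#' (second / first); and the per-species sets of families lost to zero
#' since the reference node, with the size of their intersection.
#'
#' @param bct a `branch_changes` data.frame.
#' @param counts complete `family_counts` matrix.
#' @param species_pair character vector of two leaf names.
#' @param reference_node label of an ancestor node (default: the tree root
#'   implied by `tree`).
#' @param tree labelled rooted [ape::phylo] tree.
#' @return list of class `species_pair_summary`.
#' @export
species_pair_summary <- function(bct, counts, species_pair, tree,
                                 reference_node = NULL) {
  if (length(species_pair) != 2) stop("species_pair must name two leaves")
  if (!all(species_pair %in% tree$tip.label)) {
    stop("species_pair entries must be tree leaves: ",
         paste(setdiff(species_pair, tree$tip.label), collapse = ", "))
  }
  if (is.null(reference_node)) {
    reference_node <- all_node_labels(tree)[length(tree$tip.label) + 1L]
  }
  ref <- counts[, reference_node]
  per_species <- lapply(species_pair, function(sp) {
    leaf <- counts[, sp]
    present <- leaf > 0
    row <- bct[bct$child == sp, ]
    lost <- rownames(counts)[ref > 0 & leaf == 0]
    list(
      species = sp,
      fraction_changed = if (any(present)) {
        mean(leaf[present] != ref[present])
      } else NA_real_,
      genes_gained = row$genes_gained,
      genes_lost = row$genes_lost,
      families_lost = lost
    )
  })
  a <- per_species[[1]]; b <- per_species[[2]]
  structure(
    list(
      species = species_pair,
      reference_node = reference_node,
      fraction_changed = stats::setNames(
        c(a$fraction_changed, b$fraction_changed), species_pair),
      genes_gained = stats::setNames(
        c(a$genes_gained, b$genes_gained), species_pair),
      genes_lost = stats::setNames(
        c(a$genes_lost, b$genes_lost), species_pair),
      gain_ratio = a$genes_gained / b$genes_gained,
      loss_ratio = b$genes_lost / a$genes_lost,
      families_lost = stats::setNames(
        list(a$families_lost, b$families_lost), species_pair),
      n_lost_overlap = length(intersect(a$families_lost, b$families_lost))
    ),
    class = "species_pair_summary"
  )
}

#' @export
print.species_pair_summary <- function(x, ...) {
  cat("species_pair_summary vs", x$reference_node, "\n")
  for (sp in x$species) {
    cat(sprintf(
      "  %s: %.1f%% families changed, +%d / -%d gene copies, %d families lost\n",
      sp, 100 * x$fraction_changed[[sp]], x$genes_gained[[sp]],
      x$genes_lost[[sp]], length(x$families_lost[[sp]])))
  }
  cat(sprintf("  gain ratio %s/%s = %.3g, loss ratio %s/%s = %.3g, lost-set overlap = %d\n",
              x$species[1], x$species[2], x$gain_ratio,
              x$species[2], x$species[1], x$loss_ratio, x$n_lost_overlap))
  invisible(x)
}
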