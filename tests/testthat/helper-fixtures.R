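# Shared fixtures and independent oracles. Oracles deliberately use brute
# force (full enumeration, direct summation) and never call the package
# code paths they check.

toy_tree <- function() {
  label_internal_nodes(ape::read.tree(text = "((A,B)X,(C,D)Y)R;"))
}

toy_clades <- function() {
  clade_map(list(All = c("A", "B", "C", "D"), X = c("A", "B")))
}

# random orthogroup table over given species; each orthogroup possesses a
# random nonempty species subset with 1..3 genes each
random_og_table <- function(species, n_og, seed) {
  set.seed(seed)
  membership <- lapply(seq_len(n_og), function(i) {
    k <- sample(seq_along(species), 1)
    poss <- sample(species, k)
    mm <- lapply(species, function(sp) {
      if (sp %in% poss) {
        paste0(sp, "_og", i, "_", seq_len(sample(1:3, 1)))
      } else character(0)
    })
    names(mm) <- species
    mm
  })
  orthogroup_table(paste0("OG", seq_len(n_og)), membership, species)
}

random_labelled_tree <- function(n, seed) {
  set.seed(seed)
  label_internal_nodes(ape::rtree(n, tip.label = paste0("t", seq_len(n))))
}

# brute-force MRCA: scan every tree node for the smallest tip-superset
bf_mrca <- function(tree, tips) {
  sets <- node_tip_sets(tree)
  super <- names(sets)[vapply(sets, function(s) all(tips %in% s), logical(1))]
  super[which.min(lengths(sets[super]))]
}

# brute-force confinement flags against every clade set
bf_confined <- function(possessors, clade_sets) {
  vapply(clade_sets, function(s) all(possessors %in% s), logical(1))
}

# brute-force exclusive overlap counts by scanning every orthogroup
bf_overlaps <- function(og_table, groups) {
  pres <- og_gene_counts(og_table) > 0
  res <- list()
  for (og in rownames(pres)) {
    poss <- colnames(pres)[pres[og, ]]
    in_groups <- names(groups)[vapply(groups, function(g) {
      length(intersect(poss, g)) > 0
    }, logical(1))]
    if (length(in_groups) == 0) next
    key <- paste(in_groups, collapse = "+")
    res[[key]] <- (res[[key]] %||% 0L) + 1L
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive linear-cost parsimony: minimum total |parent - child| over all
# internal-state assignments; returns min cost and the tie-broken states
# (smallest root, then smallest per node root-to-tip, via lexicographic
# search in root-first node order)
bf_sankoff <- function(tree, leaf_counts, max_state) {
  labs <- all_node_labels(tree)
  ntip <- length(tree$tip.label)
  internal <- (ntip + 1):(ntip + tree$Nnode)
  bt <- branch_table(tree)
  grid <- expand.grid(rep(list(0:max_state), length(internal)))
  cost_of <- function(states) {
    cnt <- c(leaf_counts[tree$tip.label], stats::setNames(states, labs[internal]))
    sum(abs(cnt[bt$child] - cnt[bt$parent]))
  }
  costs <- apply(grid, 1, function(s) cost_of(as.integer(s)))
  best <- min(costs)
  # tie-break: root-to-tip smallest = lexicographic minimum over states in
  # preorder node order (subtree choices are independent given the parent)
  minimizers <- grid[costs == best, , drop = FALSE]
  pre <- ape::reorder.phylo(tree, "postorder")$edge
  pre <- pre[rev(seq_len(nrow(pre))), , drop = FALSE]
  node_order <- unique(c(setdiff(pre[, 1], pre[, 2]), pre[, 2]))
  node_order <- node_order[node_order > ntip]
  col_order <- match(node_order, internal)
  ord <- do.call(order, as.list(minimizers[, col_order, drop = FALSE]))
  list(cost = best,
       states = stats::setNames(as.integer(minimizers[ord[1], ]),
                                labs[internal]))
}

# closed-form Welch statistic
bf_welch <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# hypergeometric upper tail by direct summation of the mass function,
# computed from log-binomial coefficients
bf_hyper_upper <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  xs <- k:hi
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# Benjamini-Hochberg step-up applied by hand
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# gene identifiers of one species in an orthogroup table
species_genes <- function(og_table, sp) {
  unlist(lapply(og_table$membership, function(mm) mm[[sp]]),
         use.names = FALSE)
}

# a marker table where every row passes the default filter
passing_markers <- function(genes, clusters) {
  df <- data.frame(gene = genes, cluster = clusters,
                   avg_log2FC = 1, p_val_adj = 0.001,
                   pct_in = 0.8, pct_out = 0.1, stringsAsFactors = FALSE)
  class(df) <- c("marker_table", "data.frame")
  df
}
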