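# Macrosynteny between two genomes from shared orthogroup content:
# scaffold x scaffold shared-orthogroup matrix, hypergeometric enrichment
# with BH correction, linkage groups as connected components of the
# significant-pair graph, and dot-plot coordinates.

#' Shared-orthogroup matrix for a genome pair
#'
#' Orthogroups are collapsed to presence per scaffold (multi-copy genes
#' count once); orthogroups placed on more than `max_scaffolds_per_og`
#' scaffolds in either species are excluded as promiscuous (repeat-family
#' guard). The universe N is the number of distinct orthogroups with at
#' least one placed gene in both species after filtering.
#'
#' @param posA,posB single-species `gene_positions` tables (see
#'   [read_gene_positions()]).
#' @param gene_to_og named character vector gene -> orthogroup id; genes it
#'   does not cover are dropped with a reported count.
#' @param max_scaffolds_per_og promiscuity cap (default 5).
#' @return object of class `shared_og_matrix`: list with `counts`
#'   (matrix, scaffolds of A x scaffolds of B), `margin_a`, `margin_b`
#'   (per-scaffold distinct-orthogroup counts), `N`, `species`
#'   and `placements` (per species: data.frame og, scaffold, gene, start,
#'   restricted to the shared universe).
#' @export
shared_og_matrix <- function(posA, posB, gene_to_og,
                             max_scaffolds_per_og = 5) {
  sp <- c(unique(posA$species), unique(posB$species))
  if (length(sp) != 2) stop("posA and posB must each hold a single species")
  place <- function(pos) {
    og <- unname(gene_to_og[pos$gene])
    dropped <- sum(is.na(og))
    if (dropped > 0) {
      message("shared_og_matrix: ", dropped,
              " placed gene(s) not covered by gene_to_og; dropped")
    }
    data.frame(og = og[!is.na(og)], scaffold = pos$scaffold[!is.na(og)],
               gene = pos$gene[!is.na(og)], start = pos$start[!is.na(og)],
               stringsAsFactors = FALSE)
  }
  pa <- place(posA)
  pb <- place(posB)
  promiscuous <- function(p) {
    u <- unique(p[, c("og", "scaffold")])
    tab <- table(u$og)
    names(tab)[tab > max_scaffolds_per_og]
  }
  bad <- union(promiscuous(pa), promiscuous(pb))
  if (length(bad) > 0) {
    message("shared_og_matrix: excluded ", length(bad),
            " promiscuous orthogroup(s) on > ", max_scaffolds_per_og,
            " scaffolds")
    pa <- pa[!(pa$og %in% bad), , drop = FALSE]
    pb <- pb[!(pb$og %in% bad), , drop = FALSE]
  }
  universe <- intersect(unique(pa$og), unique(pb$og))
  if (length(universe) == 0) stop("empty overlap universe (N = 0)")
  pa <- pa[pa$og %in% universe, , drop = FALSE]
  pb <- pb[pb$og %in% universe, , drop = FALSE]
  ua <- unique(pa[, c("og", "scaffold")])
  ub <- unique(pb[, c("og", "scaffold")])
  pairs <- merge(ua, ub, by = "og", suffixes = c("_a", "_b"))
  counts <- table(factor(pairs$scaffold_a, levels = sort(unique(ua$scaffold))),
                  factor(pairs$scaffold_b, levels = sort(unique(ub$scaffold))))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  structure(
    list(counts = counts,
         margin_a = vapply(split(ua$og, ua$scaffold),
                           function(o) length(unique(o)), integer(1)),
         margin_b = vapply(split(ub$og, ub$scaffold),
                           function(o) length(unique(o)), integer(1)),
         N = length(universe),
         species = sp,
         placements = stats::setNames(list(pa, pb), sp)),
    class = "shared_og_matrix"
  )
}

#' Hypergeometric enrichment test for every scaffold pair
#'
#' For scaffold pair (a, b) with k shared orthogroups, K on a, n on b and
#' universe N, the upper-tail p = P(X >= k), X ~ Hypergeometric(N, K, n).
#' Benjamini-Hochberg correction is applied across all tested pairs
#' (pairs with k = 0 are untested).
#'
#' @param m a [shared_og_matrix()].
#' @param fdr FDR level in (0, 1); default 0.05.
#' @return data.frame of class `pair_tests`: scaffold_a, scaffold_b, k, K,
#'   n, N, p, q, significant.
#' @export
test_scaffold_pairs <- function(m, fdr = 0.05) {
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1) {
    stop("fdr must lie in (0, 1)")
  }
  idx <- which(m$counts >= 1, arr.ind = TRUE)
  sa <- rownames(m$counts)[idx[, 1]]
  sb <- colnames(m$counts)[idx[, 2]]
  k <- m$counts[idx]
  K <- unname(m$margin_a[sa])
  n <- unname(m$margin_b[sb])
  p <- stats::phyper(k - 1, K, m$N - K, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(scaffold_a = sa, scaffold_b = sb,
                    k = k, K = K, n = n, N = m$N,
                    p = p, q = q, significant = q <= fdr,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$scaffold_a, out$scaffold_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fdr") <- fdr
  class(out) <- c("pair_tests", "data.frame")
  out
}

#' Linkage groups and dot-plot coordinates from significant scaffold pairs
#'
#' Builds a graph on the scaffolds of both species with significant pairs
#' as edges; connected components are the putative linkage groups,
#' numbered by descending total placed-gene count. Scaffolds on no
#' significant pair come out as singleton groups (with a warning when no
#' pair at all is significant). Dot-plot ranks place every shared-universe
#' gene along each species' axis, ordered by linkage group, then scaffold
#' gene count (descending), then scaffold id, then gene start.
#'
#' @param tests a [test_scaffold_pairs()] result.
#' @param m the [shared_og_matrix()] the tests came from.
#' @return list of class `linkage_groups`: `groups` (data.frame species,
#'   scaffold, group) and `dotplot` (data.frame og, scaffold_a, scaffold_b,
#'   rank_a, rank_b).
#' @export
linkage_groups <- function(tests, m) {
  tag <- function(side, sc) sprintf("%s:%s", side, sc)
  all_sc <- c(tag("A", rownames(m$counts)), tag("B", colnames(m$counts)))
  sig <- tests[tests$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    warning("no significant scaffold pair; every scaffold is a singleton")
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = tag("A", sig$scaffold_a),
               to = tag("B", sig$scaffold_b)),
    directed = FALSE,
    vertices = data.frame(name = all_sc)
  )
  comp <- igraph::components(g)$membership
  # gene counts per scaffold from the shared-universe placements
  gene_count <- function(sp, sc) {
    p <- m$placements[[sp]]
    sum(p$scaffold == sc)
  }
  sc_df <- data.frame(
    tag = all_sc,
    species = c(rep(m$species[1], nrow(m$counts)),
                rep(m$species[2], ncol(m$counts))),
    scaffold = c(rownames(m$counts), colnames(m$counts)),
    component = unname(comp[all_sc]),
    stringsAsFactors = FALSE
  )
  sc_df$n_genes <- mapply(gene_count, sc_df$species, sc_df$scaffold)
  comp_size <- tapply(sc_df$n_genes, sc_df$component, sum)
  ord <- order(-comp_size, as.integer(names(comp_size)))
  renum <- stats::setNames(seq_along(ord), names(comp_size)[ord])
  sc_df$group <- unname(renum[as.character(sc_df$component)])
  sc_df <- sc_df[order(sc_df$group, -sc_df$n_genes, sc_df$scaffold), ,
                 drop = FALSE]
  ranks <- lapply(m$species, function(sp) {
    scs <- sc_df$scaffold[sc_df$species == sp]
    p <- m$placements[[sp]]
    p <- p[order(match(p$scaffold, scs), p$start, p$gene), , drop = FALSE]
    p$rank <- seq_len(nrow(p))
    p
  })
  names(ranks) <- m$species
  dp <- merge(ranks[[1]][, c("og", "scaffold", "rank")],
              ranks[[2]][, c("og", "scaffold", "rank")],
              by = "og", suffixes = c("_a", "_b"))
  dp <- dp[order(dp$rank_a, dp$rank_b), , drop = FALSE]
  rownames(dp) <- NULL
  structure(
    list(groups = sc_df[, c("species", "scaffold", "group", "n_genes")],
         dotplot = dp),
    class = "linkage_groups"
  )
}
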