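# Shared-orthogroup matrices, exact hypergeometric enrichment, BH
# correction, linkage-group components and planted-truth recovery.

pos_table <- function(sp, genes, scaffolds) {
  new_gene_positions <- getFromNamespace("new_gene_positions", "orthoclades")
  new_gene_positions(species = rep(sp, length(genes)), gene = genes,
                     scaffold = scaffolds,
                     start = seq(0, by = 2000, length.out = length(genes)),
                     end = seq(1000, by = 2000, length.out = length(genes)),
                     strand = rep("+", length(genes)))
}

test_that("shared-orthogroup matrix collapses copies and counts presence", {
  g2og <- c(a1 = "og1", a2 = "og2", a3 = "og1",
            b1 = "og1", b2 = "og2")
  posA <- pos_table("spA", c("a1", "a2"), c("scA1", "scA1"))
  posB <- pos_table("spB", c("b1", "b2"), c("scB1", "scB2"))
  m <- shared_og_matrix(posA, posB, g2og)
  expect_equal(m$N, 2)
  expect_equal(m$counts["scA1", "scB1"], 1L)
  expect_equal(m$counts["scA1", "scB2"], 1L)

  # a second copy on the same scaffold still contributes once
  posA2 <- pos_table("spA", c("a1", "a2", "a3"), rep("scA1", 3))
  m2 <- shared_og_matrix(posA2, posB, g2og)
  expect_equal(m2$counts, m$counts)

  expect_error(shared_og_matrix(posA, pos_table("spB", "bX", "scB9"),
                                c(a1 = "og1", a2 = "og2", bX = "ogZ")),
               "N = 0")
})

test_that("matrix equals a triple-loop brute force on random placements", {
  for (rep in 1:5) {
    set.seed(rep + 40)
    n_og <- 30
    g2og <- stats::setNames(paste0("og", rep(1:n_og, 2)),
                            c(paste0("a", 1:n_og), paste0("b", 1:n_og)))
    posA <- pos_table("spA", paste0("a", 1:n_og),
                      sample(paste0("scA", 1:4), n_og, replace = TRUE))
    posB <- pos_table("spB", paste0("b", 1:n_og),
                      sample(paste0("scB", 1:4), n_og, replace = TRUE))
    m <- shared_og_matrix(posA, posB, g2og)
    for (sa in rownames(m$counts)) for (sb in colnames(m$counts)) {
      bf <- 0L
      for (og in paste0("og", 1:n_og)) {
        onA <- any(posA$scaffold == sa & g2og[posA$gene] == og)
        onB <- any(posB$scaffold == sb & g2og[posB$gene] == og)
        if (onA && onB) bf <- bf + 1L
      }
      expect_equal(m$counts[sa, sb], bf)
    }
  }
})

test_that("promiscuous orthogroups are excluded from matrix and universe", {
  genes_a <- paste0("a", 1:7)
  g2og <- stats::setNames(c(rep("ogP", 6), "og1"), genes_a)
  g2og <- c(g2og, bP = "ogP", b1 = "og1")
  posA <- pos_table("spA", genes_a, c(paste0("scA", 1:6), "scA1"))
  posB <- pos_table("spB", c("bP", "b1"), c("scB1", "scB1"))
  expect_message(m <- shared_og_matrix(posA, posB, g2og,
                                       max_scaffolds_per_og = 5),
                 "promiscuous")
  expect_equal(m$N, 1)
  expect_false("ogP" %in% m$placements$spA$og)
})

test_that("hypergeometric upper tails match direct mass summation", {
  p <- stats::phyper(5 - 1, 6, 10 - 6, 7, lower.tail = FALSE)
  expect_equal(p, bf_hyper_upper(5, 6, 7, 10), tolerance = 1e-12)
  # degenerate: the only support point
  expect_equal(stats::phyper(4 - 1, 4, 0, 4, lower.tail = FALSE), 1)
  for (rep in 1:50) {
    set.seed(rep)
    N <- sample(2:200, 1)
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 bf_hyper_upper(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(stats::p.adjust(rep(0.01, 7), "BH"), rep(0.01, 7))
  for (rep in 1:20) {
    set.seed(rep + 60)
    p <- stats::runif(sample(3:40, 1))
    expect_equal(stats::p.adjust(p, "BH"), bf_bh(p), tolerance = 1e-14)
    q <- stats::p.adjust(p, "BH")
    expect_true(all(q[order(p)] == cummax(q[order(p)])))  # monotone in p
  }
})

test_that("pair tests satisfy their contract on a simulated genome pair", {
  ex <- example_study_tree()
  sim <- simulate_gene_content(ex$tree, 300, loss_prob = 0.05,
                               drift_prob = 0.2, seed = 81)
  pair <- c("Hydractinia_symbiolongicarpus", "Hydractinia_echinata")
  gen <- simulate_genomes(sim, pair, n_groups = 4,
                          translocation_rate = 0.05, seed = 82)
  m <- shared_og_matrix(gen$positions[[1]], gen$positions[[2]],
                        gene_to_og_map(sim$orthogroups))
  tests <- test_scaffold_pairs(m, fdr = 0.05)
  expect_true(all(tests$p > 0 & tests$p <= 1))
  expect_true(all(tests$q >= tests$p))
  expect_true(all(tests$q[tests$significant] <= 0.05))
  expect_true(all(tests$k >= 1))
  expect_error(test_scaffold_pairs(m, fdr = 1.5), "fdr")
})

test_that("swapping the two species transposes everything", {
  ex <- example_study_tree()
  sim <- simulate_gene_content(ex$tree, 250, loss_prob = 0.05,
                               drift_prob = 0.2, seed = 83)
  pair <- c("Hydractinia_symbiolongicarpus", "Hydractinia_echinata")
  gen <- simulate_genomes(sim, pair, n_groups = 3,
                          translocation_rate = 0.1, seed = 84)
  g2og <- gene_to_og_map(sim$orthogroups)
  m_ab <- shared_og_matrix(gen$positions[[1]], gen$positions[[2]], g2og)
  m_ba <- shared_og_matrix(gen$positions[[2]], gen$positions[[1]], g2og)
  expect_equal(m_ab$counts, t(m_ba$counts))
  t_ab <- test_scaffold_pairs(m_ab)
  t_ba <- test_scaffold_pairs(m_ba)
  key_ab <- paste(t_ab$scaffold_a, t_ab$scaffold_b)
  key_ba <- paste(t_ba$scaffold_b, t_ba$scaffold_a)
  ord <- match(key_ab, key_ba)
  expect_equal(t_ab$p, t_ba$p[ord])
  lg_ab <- linkage_groups(t_ab, m_ab)
  lg_ba <- linkage_groups(t_ba, m_ba)
  # identical partitions regardless of group numbering
  part <- function(lg) {
    g <- lg$groups
    canon <- vapply(split(paste(g$species, g$scaffold), g$group),
                    function(v) paste(sort(v), collapse = "|"),
                    character(1))
    sort(unname(canon))
  }
  expect_equal(part(lg_ab), part(lg_ba))
})

test_that("connected components group scaffolds; no signal means singletons", {
  mk_tests <- function(pairs, sig) {
    data.frame(scaffold_a = pairs[, 1], scaffold_b = pairs[, 2],
               k = 3L, K = 3L, n = 3L, N = 10L, p = 0.001, q = 0.001,
               significant = sig, stringsAsFactors = FALSE)
  }
  m <- list(counts = matrix(1L, 2, 2,
                            dimnames = list(c("a1", "a2"), c("b1", "b2"))),
            species = c("spA", "spB"),
            placements = list(
              spA = data.frame(og = c("og1", "og2"), scaffold = c("a1", "a2"),
                               gene = c("ga1", "ga2"), start = c(0, 0)),
              spB = data.frame(og = c("og1", "og2"), scaffold = c("b1", "b2"),
                               gene = c("gb1", "gb2"), start = c(0, 0))))
  names(m$placements) <- m$species
  tests <- mk_tests(rbind(c("a1", "b1"), c("a2", "b1")), c(TRUE, TRUE))
  lg <- linkage_groups(tests, m)
  grp <- lg$groups
  one <- grp$group[grp$scaffold %in% c("a1", "a2", "b1")]
  expect_length(unique(one), 1)
  expect_false(grp$group[grp$scaffold == "b2"] %in% one)

  none <- mk_tests(rbind(c("a1", "b1")), FALSE)
  expect_warning(lg0 <- linkage_groups(none, m), "singleton")
  expect_equal(sort(unique(lg0$groups$group)), 1:4)
})

test_that("planted linkage groups are recovered exactly at zero rearrangement", {
  ex <- example_study_tree()
  sim <- simulate_gene_content(ex$tree, 2000, loss_prob = 0.05,
                               drift_prob = 0.2, seed = 85)
  pair <- c("Hydractinia_symbiolongicarpus", "Hydractinia_echinata")
  gen <- simulate_genomes(sim, pair, n_groups = 5,
                          translocation_rate = 0, inversion_rate = 0,
                          seed = 86)
  m <- shared_og_matrix(gen$positions[[1]], gen$positions[[2]],
                        gene_to_og_map(sim$orthogroups))
  tests <- test_scaffold_pairs(m)
  lg <- linkage_groups(tests, m)
  grp <- lg$groups
  # truth: the ancestral group is encoded in the simulated scaffold name
  truth <- as.integer(sub(".*_sc0?(\\d+)_\\d+$", "\\1", grp$scaffold))
  tab <- table(grp$group, truth)
  expect_true(all(rowSums(tab > 0) == 1))  # each component pure
  expect_true(all(colSums(tab > 0) == 1))  # each planted group uncut
  expect_equal(mclust::adjustedRandIndex(grp$group, truth), 1.0)

  # recovery degrades (non-strictly) as the translocation rate grows
  ari_at <- vapply(c(0, 0.3, 0.9), function(rate) {
    g <- simulate_genomes(sim, pair, n_groups = 5,
                          translocation_rate = rate, seed = 87)
    mm <- shared_og_matrix(g$positions[[1]], g$positions[[2]],
                           gene_to_og_map(sim$orthogroups))
    lg2 <- suppressWarnings(linkage_groups(test_scaffold_pairs(mm), mm))
    tr <- as.integer(sub(".*_sc0?(\\d+)_\\d+$", "\\1", lg2$groups$scaffold))
    mclust::adjustedRandIndex(lg2$groups$group, tr)
  }, numeric(1))
  expect_true(all(diff(ari_at) <= 1e-9))
})

test_that("dot-plot ranks are unique per axis and rows lie on shared orthogroups", {
  ex <- example_study_tree()
  sim <- simulate_gene_content(ex$tree, 250, loss_prob = 0.05,
                               drift_prob = 0.2, seed = 88)
  pair <- c("Hydractinia_symbiolongicarpus", "Hydractinia_echinata")
  gen <- simulate_genomes(sim, pair, n_groups = 4,
                          translocation_rate = 0.05, inversion_rate = 0.2,
                          seed = 89)
  g2og <- gene_to_og_map(sim$orthogroups)
  m <- shared_og_matrix(gen$positions[[1]], gen$positions[[2]], g2og)
  lg <- linkage_groups(test_scaffold_pairs(m), m)
  dp <- lg$dotplot
  # rank is a permutation of placements per axis
  pa <- m$placements[[1]]
  expect_setequal(unique(dp$rank_a), seq_len(nrow(pa)))
  for (r in sample(nrow(dp), 20)) {
    og <- dp$og[r]
    expect_true(og %in% pa$og[pa$scaffold == dp$scaffold_a[r]])
    pb <- m$placements[[2]]
    expect_true(og %in% pb$og[pb$scaffold == dp$scaffold_b[r]])
  }
})
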