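# Marker filtering, ladder-category annotation, group profiles and the
# stem-cell sharing histogram.

mk_row <- function(gene, cluster, l2fc, p, pin = 0.5, pout = 0.1) {
  data.frame(gene = gene, cluster = cluster, avg_log2FC = l2fc,
             p_val_adj = p, pct_in = pin, pct_out = pout,
             stringsAsFactors = FALSE)
}

test_that("filtering keeps exactly the rows satisfying every criterion", {
  mt <- rbind(mk_row("g1", "C1", 0.7, 0.01),
              mk_row("g2", "C1", 0.3, 0.01),
              mk_row("g3", "C1", 0.9, 0.2))
  class(mt) <- c("marker_table", "data.frame")
  crit <- filter_criteria(max_p_adj = 0.05, min_log2fc = 0.5,
                          min_pct_in = 0)
  kept <- filter_markers(mt, crit)
  expect_equal(kept$gene, "g1")
  expect_equal(attr(kept, "per_cluster")$dropped, 2L)

  lax <- filter_criteria(max_p_adj = 1, min_log2fc = -10,
                         min_pct_in = 0, positive_only = FALSE)
  expect_equal(nrow(filter_markers(mt, lax)), nrow(mt))
  strict <- filter_criteria(max_p_adj = 0.0001)
  expect_warning(filter_markers(mt, strict), "no markers")
})

test_that("planted pass/fail labels are recovered exactly by the filter", {
  strata <- stats::setNames(rep(c("x", "y"), each = 200),
                            paste0("g", 1:400))
  sim <- simulate_markers(strata,
                          mixtures = list(C1 = c(x = 0.5, y = 0.5),
                                          C2 = c(x = 0.2, y = 0.8)),
                          n_per_cluster = 80, fail_fraction = 0.3,
                          seed = 9)
  kept <- suppressWarnings(filter_markers(sim$markers))
  key <- function(df) paste(df$gene, df$cluster)
  expect_setequal(key(kept), key(sim$truth[sim$truth$passes, ]))
})

# an assignment over the study-shaped tree, for ladder annotation
study_assignment <- function(seed, n_families = 250) {
  ex <- example_study_tree()
  sim <- simulate_gene_content(ex$tree, n_families, loss_prob = 0.2,
                               drift_prob = 0.2, seed = seed)
  list(ex = ex, sim = sim,
       asg = classify_orthogroups(sim$orthogroups, ex$tree, ex$clades))
}

ladder6 <- c("Hydractinia", "Hydractinia_Clytia", "Hydrozoa",
             "Medusozoa", "Cnidaria", "Metazoa")
focal <- "Hydractinia_symbiolongicarpus"

test_that("marker categories equal the brute-force smallest containing ladder clade", {
  st <- study_assignment(31, 400)
  g2og <- gene_to_og_map(st$sim$orthogroups)
  genes <- species_genes(st$sim$orthogroups, focal)
  set.seed(32)
  pick <- sample(genes, min(500, length(genes)))
  mt <- passing_markers(pick, "C1")
  ann <- assign_marker_categories(mt, st$asg, ladder6, g2og)
  for (j in seq_along(pick)) {
    og <- unname(g2og[pick[j]])
    i <- match(og, st$asg$table$og_id)
    expected <- if (st$asg$table$n_species[i] == 1) {
      "species_specific"
    } else {
      hit <- ladder6[vapply(ladder6, function(cl) {
        all(st$asg$possessors[[i]] %in% st$ex$clades$sets[[cl]])
      }, logical(1))]
      if (length(hit) == 0) "other_multispecies" else hit[1]
    }
    expect_identical(as.character(ann$category[j]), expected)
  }
  # a gene absent from the mapping is not-assigned
  orphan <- passing_markers("no_such_gene", "C1")
  ann2 <- assign_marker_categories(orphan, st$asg, ladder6, g2og)
  expect_identical(as.character(ann2$category), "not_assigned")
})

test_that("a genus-restricted orthogroup yields a genus-confined marker", {
  ex <- example_study_tree()
  sp <- ex$tree$tip.label
  mm <- lapply(sp, function(s) {
    if (s %in% c("Hydractinia_symbiolongicarpus", "Hydractinia_echinata")) {
      paste0(s, "_g1")
    } else character(0)
  })
  names(mm) <- sp
  tab <- orthogroup_table("OGgenus", list(mm), sp)
  asg <- classify_orthogroups(tab, ex$tree, ex$clades)
  ann <- assign_marker_categories(
    passing_markers("Hydractinia_symbiolongicarpus_g1", "C1"),
    asg, ladder6, gene_to_og_map(tab))
  expect_identical(as.character(ann$category), "Hydractinia")
})

test_that("group profiles sum to one and the lineage fraction uses the full denominator", {
  st <- study_assignment(41, 400)
  g2og <- gene_to_og_map(st$sim$orthogroups)
  genes <- species_genes(st$sim$orthogroups, focal)
  mt <- passing_markers(c(genes[1:30], "orphan_gene"),
                        rep(c("C1", "C2"), length.out = 31))
  ann <- assign_marker_categories(mt, st$asg, ladder6, g2og)
  prof <- group_profiles(ann, c(C1 = "C1", C2 = "C2"))
  sums <- tapply(prof$proportion, prof$group, sum)
  expect_equal(as.vector(sums), rep(1, 2), tolerance = 1e-9)
  counts <- tapply(prof$n, prof$group, sum)
  expect_equal(sum(counts), nrow(ann))
  expect_error(group_profiles(ann, c(C1 = "C1")), "C2")

  # hand-checkable fraction: 4 markers, one lineage-specific
  lvl <- levels(ann$category)
  toy <- ann[1:4, ]
  toy$cluster <- "C9"
  toy$category <- factor(c("Cnidaria", "Metazoa", "other_multispecies",
                           "not_assigned"), levels = lvl)
  p <- group_profiles(toy, c(C9 = "grp"))
  expect_equal(attr(p, "summary")$lineage_specific_fraction, 0.25)
  p2 <- group_profiles(toy, c(C9 = "grp"), denominator = "assigned_only")
  expect_equal(attr(p2, "summary")$lineage_specific_fraction, 1 / 3)
})

test_that("profiles are invariant to marker row order and cluster relabeling", {
  st <- study_assignment(43, 300)
  g2og <- gene_to_og_map(st$sim$orthogroups)
  genes <- species_genes(st$sim$orthogroups, focal)
  mt <- passing_markers(genes[1:40], rep(c("C1", "C2"), 20))
  ann <- assign_marker_categories(mt, st$asg, ladder6, g2og)
  set.seed(44)
  shuf <- ann[sample(nrow(ann)), ]
  relab <- shuf
  relab$cluster <- c(C1 = "K1", C2 = "K2")[relab$cluster]
  p1 <- group_profiles(ann, c(C1 = "g1", C2 = "g2"))
  p2 <- group_profiles(relab, c(K1 = "g1", K2 = "g2"))
  ord <- function(p) p[order(p$group, p$category), c("group", "category",
                                                     "n", "proportion")]
  expect_equal(ord(p1), ord(p2), ignore_attr = TRUE)
})

test_that("stem-cell sharing histogram conserves the assigned-marker count", {
  st <- study_assignment(47, 400)
  g2og <- gene_to_og_map(st$sim$orthogroups)
  genes <- species_genes(st$sim$orthogroups, focal)
  mt <- passing_markers(c(genes[1:25], "orphanA", "orphanB"),
                        rep(c("C6", "C7", "C1"), length.out = 27))
  ann <- assign_marker_categories(mt, st$asg, ladder6, g2og)
  res <- icell_sharing_histogram(ann, c("C6", "C7"), st$asg,
                                 min_shared = 4)
  in_clusters <- ann[ann$cluster %in% c("C6", "C7") & !is.na(ann$og_id), ]
  in_clusters <- in_clusters[!duplicated(in_clusters$gene), ]
  expect_equal(sum(res$histogram), res$n_assigned)
  expect_equal(res$n_assigned, nrow(in_clusters))
  expect_equal(res$fraction_widely_shared,
               mean(in_clusters$n_possessor_species >= 4))
  expect_error(icell_sharing_histogram(ann, "C99", st$asg), "C99")
  empty <- icell_sharing_histogram(
    assign_marker_categories(passing_markers("orphanC", "C5"),
                             st$asg, ladder6, g2og),
    "C5", st$asg)
  expect_equal(empty$n_assigned, 0L)
  expect_length(empty$histogram, 0)
})

test_that("whole-dataset marker profile agrees with the five-way gene categories", {
  st <- study_assignment(53, 400)
  g2og <- gene_to_og_map(st$sim$orthogroups)
  expressed <- c(species_genes(st$sim$orthogroups, focal),
                 paste0(focal, "|orphan", 1:23))
  mt <- passing_markers(expressed, "all")
  ann <- assign_marker_categories(mt, st$asg, ladder6, g2og)
  prof <- group_profiles(ann, c(all = "all"))
  # collapse the ladder onto the five-way partition
  collapse <- c(not_assigned = "unassigned",
                species_specific = "species_specific",
                Hydractinia = "phylum_specific",
                Hydractinia_Clytia = "phylum_specific",
                Hydrozoa = "phylum_specific",
                Medusozoa = "phylum_specific",
                Cnidaria = "phylum_specific",
                Metazoa = "metazoan_specific",
                other_multispecies = "other_multispecies")
  coll <- tapply(prof$proportion, collapse[as.character(prof$category)], sum)
  gc <- gene_categories(st$sim$orthogroups, st$asg, focal, expressed)
  expect_equal(coll[names(gc$proportions)], gc$proportions,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("planted per-cluster mixtures are recovered within the binomial 99% CI", {
  # gene pool with two known strata: 900 genus-restricted orthogroups and
  # 900 shared pan-metazoan orthogroups, one focal gene each
  ex <- example_study_tree()
  sp <- ex$tree$tip.label
  empty <- stats::setNames(rep(list(character(0)), length(sp)), sp)
  mk_og <- function(i, possessors) {
    mm <- empty
    for (s in possessors) mm[[s]] <- paste0(s, "|og", i)
    mm
  }
  membership <- c(
    lapply(1:900, function(i) mk_og(i, c(focal, "Hydractinia_echinata"))),
    lapply(901:1800, function(i) mk_og(i, c(focal, "Homo_sapiens")))
  )
  tab <- orthogroup_table(paste0("OG", 1:1800), membership, sp)
  asg <- classify_orthogroups(tab, ex$tree, ex$clades)
  g2og <- gene_to_og_map(tab)
  strata <- stats::setNames(
    rep(c("Hydractinia", "Metazoa"), each = 900),
    paste0(focal, "|og", 1:1800))
  mix <- c(Hydractinia = 0.5, Metazoa = 0.5)
  n <- 1000
  sim <- simulate_markers(strata, list(CL = mix), n_per_cluster = n,
                          fail_fraction = 0, seed = 62)
  ann <- assign_marker_categories(sim$markers, asg, ladder6, g2og)
  prof <- group_profiles(ann, c(CL = "CL"))
  for (cat in names(mix)) {
    obs <- prof$n[prof$category == cat & prof$group == "CL"]
    ci <- stats::qbinom(c(0.005, 0.995), n, mix[[cat]])
    expect_gte(obs, ci[1])
    expect_lte(obs, ci[2])
  }
  # the emitted truth matches the emitted table exactly
  recomputed <- stats::setNames(as.character(ann$category), ann$gene)
  expect_identical(unname(recomputed[sim$truth$gene]),
                   sim$truth$category)
})
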