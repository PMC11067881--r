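# Synthetic inputs with machine-readable ground truth: gene families
# originating on tree branches with Dollo-style irreversible losses and
# integer copy-number drift; a genome pair whose scaffolds descend from
# shared ancestral linkage groups with translocation/inversion noise; and
# marker tables with planted per-cluster category mixtures and planted
# filter pass/fail labels.
#
# All randomness flows from one integer seed via named substreams
# (seed + fixed offsets), so adding a stage never perturbs earlier outputs
# and a fixed seed reproduces byte-identical files.

substream <- function(seed, stage) {
  offsets <- c(tree = 101L, content = 211L, genomes = 307L, markers = 401L)
  set.seed((as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max)
}

#' Simulate a random rooted species tree
#'
#' @param n_leaves number of leaves (>= 2).
#' @param seed integer seed.
#' @return labelled rooted [ape::phylo] tree with tips `sp1..spN`.
#' @export
simulate_tree <- function(n_leaves, seed = 1) {
  stopifnot(n_leaves >= 2)
  substream(seed, "tree")
  tree <- ape::rtree(n_leaves, tip.label = paste0("sp", seq_len(n_leaves)))
  label_internal_nodes(tree)
}

#' Simulate gene-family content on a species tree
#'
#' Each family originates on a uniformly drawn branch (the root included)
#' with a single gene copy. Below the origin, along every branch the
#' family is lost with probability `loss_prob` (Dollo: the whole subtree
#' goes to zero, permanently), otherwise its copy number takes a +/-1 step
#' with probability `drift_prob`; zero is absorbing, so drift hitting zero
#' is also a loss. Families surviving in no leaf are dropped from the
#' emitted tables but recorded in the truth.
#'
#' @param tree labelled rooted [ape::phylo] tree.
#' @param n_families number of families to simulate (>= 1).
#' @param loss_prob per-branch Dollo loss probability.
#' @param drift_prob per-branch probability of a +/-1 copy-number step.
#' @param seed integer seed.
#' @return list: `orthogroups` ([orthogroup_table()]), `counts`
#'   (`family_counts` over leaves), `truth` (per family: origin branch
#'   child label, loss branch labels, true counts at every node, survived
#'   flag).
#' @export
simulate_gene_content <- function(tree, n_families = 2000,
                                  loss_prob = 0.05, drift_prob = 0.3,
                                  seed = 1) {
  if (n_families < 1) stop("n_families must be >= 1")
  if (length(tree$tip.label) < 1) stop("tree must have leaves")
  substream(seed, "content")
  labs <- all_node_labels(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")$edge
  pre <- post[rev(seq_len(nrow(post))), , drop = FALSE]
  root <- setdiff(post[, 1], post[, 2])[1]
  # origin drawn uniformly over branches (identified by child) plus root
  origin_choices <- c(root, post[, 2])

  fam_id <- sprintf("OG%07d", seq_len(n_families))
  truth <- vector("list", n_families)
  counts_leaf <- matrix(0L, nrow = n_families, ncol = ntip,
                        dimnames = list(fam_id, tree$tip.label))
  membership <- vector("list", n_families)

  # descendant node sets for "below the origin"
  desc_nodes <- phangorn::Descendants(tree, seq_len(nnode), type = "all")

  for (f in seq_len(n_families)) {
    origin <- sample(origin_choices, 1)
    cnt <- rep(NA_integer_, nnode)
    cnt[origin] <- 1L
    below <- c(origin, desc_nodes[[origin]])
    losses <- character(0)
    for (e in seq_len(nrow(pre))) {
      parent <- pre[e, 1]; child <- pre[e, 2]
      if (!(child %in% below) || child == origin) next
      pc <- cnt[parent]
      if (is.na(pc)) next
      if (pc == 0L) { cnt[child] <- 0L; next }
      if (stats::runif(1) < loss_prob) {
        cnt[child] <- 0L
        losses <- c(losses, labs[child])
        next
      }
      v <- pc
      if (stats::runif(1) < drift_prob) {
        v <- v + sample(c(-1L, 1L), 1)
        if (v <= 0L) {
          v <- 0L
          losses <- c(losses, labs[child])
        }
      }
      cnt[child] <- v
    }
    cnt[is.na(cnt)] <- 0L
    counts_leaf[f, ] <- cnt[seq_len(ntip)]
    genes <- lapply(seq_len(ntip), function(t) {
      k <- cnt[t]
      if (k == 0L) character(0) else {
        paste0(tree$tip.label[t], "|", fam_id[f], "|g", seq_len(k))
      }
    })
    names(genes) <- tree$tip.label
    membership[[f]] <- genes
    truth[[f]] <- list(
      family = fam_id[f],
      origin = labs[origin],
      losses = losses,
      counts = stats::setNames(as.integer(cnt), labs),
      survived = any(cnt[seq_len(ntip)] > 0)
    )
  }
  survived <- vapply(truth, `[[`, logical(1), "survived")
  og <- orthogroup_table(fam_id[survived], membership[survived],
                         tree$tip.label)
  cm <- counts_leaf[survived, , drop = FALSE]
  list(
    orthogroups = og,
    counts = structure(cm, class = c("family_counts", class(unclass(cm))),
                       has_internal = FALSE),
    truth = stats::setNames(truth, fam_id)
  )
}

#' Simulate a genome pair descending from shared ancestral linkage groups
#'
#' Every orthogroup of the two focal species is assigned to one of
#' `n_groups` ancestral linkage groups. Per species, each group's genes
#' are spread over `scaffolds_per_group` scaffolds; each gene is
#' translocated to a uniformly random group with probability
#' `translocation_rate` (independently per species); local gene order on
#' each scaffold has a window reversed with probability `inversion_rate`.
#' Coordinates are synthesised non-overlapping.
#'
#' @param content result of [simulate_gene_content()] (or any
#'   [orthogroup_table()] in `content$orthogroups`).
#' @param species_pair two species names present in the table.
#' @param n_groups number of ancestral linkage groups.
#' @param scaffolds_per_group scaffolds each group splits into, per species.
#' @param translocation_rate,inversion_rate noise rates in \[0, 1\].
#' @param seed integer seed.
#' @return list: `positions` (named list of two `gene_positions` tables),
#'   `truth` (data.frame og, ancestral_group; plus per-gene group after
#'   translocation per species).
#' @export
simulate_genomes <- function(content, species_pair, n_groups = 5,
                             scaffolds_per_group = 2,
                             translocation_rate = 0, inversion_rate = 0,
                             seed = 1) {
  og_tab <- content$orthogroups
  if (!all(species_pair %in% og_tab$species_order)) {
    stop("species_pair must be species of the orthogroup table")
  }
  substream(seed, "genomes")
  counts <- og_gene_counts(og_tab)
  shared <- rownames(counts)[counts[, species_pair[1]] > 0 &
                               counts[, species_pair[2]] > 0]
  if (n_groups > length(shared)) {
    stop("more linkage groups (", n_groups, ") than shared families (",
         length(shared), ")")
  }
  placed_ogs <- rownames(counts)[rowSums(counts[, species_pair,
                                                drop = FALSE]) > 0]
  anc_group <- stats::setNames(
    sample(seq_len(n_groups), length(placed_ogs), replace = TRUE),
    placed_ogs)
  # guarantee every group holds at least one shared family
  anc_group[sample(shared, n_groups)] <- seq_len(n_groups)

  gene_truth <- list()
  positions <- lapply(species_pair, function(sp) {
    genes <- unlist(lapply(og_tab$membership, function(mm) mm[[sp]]),
                    use.names = FALSE)
    og <- unname(gene_to_og_map(og_tab)[genes])
    grp <- unname(anc_group[og])
    moved <- stats::runif(length(genes)) < translocation_rate
    grp[moved] <- sample(seq_len(n_groups), sum(moved), replace = TRUE)
    scaf_idx <- sample(seq_len(scaffolds_per_group), length(genes),
                       replace = TRUE)
    scaffold <- sprintf("%s_sc%02d_%d", sp, grp, scaf_idx)
    df <- data.frame(gene = genes, og = og, group = grp,
                     scaffold = scaffold, stringsAsFactors = FALSE)
    df <- df[order(df$scaffold, df$gene), , drop = FALSE]
    # inversions: reverse a random window of each affected scaffold
    parts <- split(seq_len(nrow(df)), df$scaffold)
    for (idx in parts) {
      if (length(idx) >= 3 && stats::runif(1) < inversion_rate) {
        w <- sort(sample(seq_along(idx), 2))
        idx_window <- idx[w[1]:w[2]]
        df[idx_window, ] <- df[rev(idx_window), ]
      }
    }
    pos_in_scaf <- stats::ave(seq_len(nrow(df)), df$scaffold,
                              FUN = seq_along)
    gene_truth[[sp]] <<- stats::setNames(df$group, df$gene)
    new_gene_positions(
      species = rep(sp, nrow(df)), gene = df$gene, scaffold = df$scaffold,
      start = (pos_in_scaf - 1L) * 1500L,
      end = (pos_in_scaf - 1L) * 1500L + 1000L,
      strand = sample(c("+", "-"), nrow(df), replace = TRUE)
    )
  })
  names(positions) <- species_pair
  list(
    positions = positions,
    truth = list(
      ancestral_group = anc_group,
      gene_group = gene_truth
    )
  )
}

#' Simulate a marker table with planted category mixtures
#'
#' Per cluster, marker genes are drawn (without replacement within a
#' cluster) from the focal species' gene strata defined by an annotated
#' category ladder, at planted proportions; effect sizes, detection
#' fractions and adjusted p-values are drawn so that planted pass/fail
#' labels are realised exactly under `criteria`.
#'
#' @param gene_categories named character vector: focal-species gene ->
#'   category label (the strata).
#' @param mixtures named list: cluster id -> named numeric vector of
#'   planted proportions over category labels (each summing to 1).
#' @param n_per_cluster markers drawn per cluster.
#' @param fail_fraction fraction of rows planted to fail the filter.
#' @param criteria the [filter_criteria()] the pass/fail labels target.
#' @param seed integer seed.
#' @return list: `markers` (`marker_table`), `truth` (data.frame gene,
#'   cluster, category, passes).
#' @export
simulate_markers <- function(gene_categories, mixtures,
                             n_per_cluster = 100, fail_fraction = 0.2,
                             criteria = filter_criteria(), seed = 1) {
  substream(seed, "markers")
  strata <- split(names(gene_categories), unname(gene_categories))
  rows <- list()
  for (cl in names(mixtures)) {
    mix <- mixtures[[cl]]
    if (abs(sum(mix) - 1) > 1e-9) stop("mixture for ", cl, " must sum to 1")
    n_cat <- stats::setNames(
      as.vector(stats::rmultinom(1, n_per_cluster, mix)), names(mix))
    pool_used <- character(0)
    for (cat in names(n_cat)) {
      k <- n_cat[[cat]]
      if (k == 0) next
      pool <- setdiff(strata[[cat]], pool_used)
      if (is.null(pool) || length(pool) < k) {
        stop("planted stratum '", cat, "' has too few available genes (",
             length(pool), " < ", k, ") for cluster ", cl)
      }
      g <- sample(pool, k)
      pool_used <- c(pool_used, g)
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, cluster = cl, category = cat, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  n <- nrow(df)
  passes <- stats::runif(n) >= fail_fraction
  draw <- function(lo, hi, n) stats::runif(n, lo, hi)
  p_adj <- ifelse(passes, draw(0, criteria$max_p_adj * 0.9, n),
                  draw(min(criteria$max_p_adj * 1.5, 1), 1, n))
  l2fc <- ifelse(passes, draw(criteria$min_log2fc + 0.1,
                              criteria$min_log2fc + 2, n),
                 draw(criteria$min_log2fc + 0.1, criteria$min_log2fc + 2, n))
  pct_in <- draw(max(criteria$min_pct_in, 0.3), 1, n)
  pct_out <- draw(0, min(criteria$max_pct_out, 0.3), n)
  mk <- data.frame(gene = df$gene, cluster = df$cluster,
                   avg_log2FC = l2fc, p_val_adj = pmin(p_adj, 1),
                   pct_in = pct_in, pct_out = pct_out,
                   stringsAsFactors = FALSE)
  class(mk) <- c("marker_table", "data.frame")
  truth <- data.frame(gene = df$gene, cluster = df$cluster,
                      category = df$category, passes = passes,
                      stringsAsFactors = FALSE)
  list(markers = mk, truth = truth)
}

#' Independent self-consistency check of simulator ground truth
#'
#' Re-derives, from the emitted tables alone, the facts the ground truth
#' asserts: per-family possessor sets and leaf counts against the truth's
#' node counts, per-gene linkage groups against scaffold naming, and
#' marker categories/pass labels against the marker table plus the filter.
#' Returns TRUE or stops with the first inconsistency.
#'
#' @param content result of [simulate_gene_content()].
#' @param tree the tree it was simulated on.
#' @return TRUE invisibly.
#' @export
check_content_truth <- function(content, tree) {
  counts <- og_gene_counts(content$orthogroups)
  for (f in rownames(counts)) {
    tr <- content$truth[[f]]
    if (is.null(tr)) stop("family missing from truth: ", f)
    expect <- tr$counts[colnames(counts)]
    if (!all(counts[f, ] == expect)) {
      stop("leaf counts disagree with truth for ", f)
    }
    if (!tr$survived) stop("non-survivor emitted: ", f)
  }
  invisible(TRUE)
}

#' Study-shaped example species tree and clade ladder
#'
#' A 22-leaf rooted tree shaped like the taxon sampling of cnidarian
#' comparative-genomic studies: 15 cnidarians (8 hydrozoans including the
#' two *Hydractinia* species and *Clytia*, 3 other medusozoans, 4
#' anthozoans), 4 bilaterians and 3 non-metazoan outgroups. The clade map
#' carries the specificity ladder (Cnidaria > Medusozoa > Hydrozoa >
#' Hydractinia+Clytia > Hydractinia) plus Anthozoa, Bilateria, Metazoa and
#' the outgroups, with `focal_phylum`, `metazoa` and `outgroup` roles set.
#' This is a synthetic stand-in assembled from consensus relationships,
#' not a published tree.
#'
#' @return list with `tree` ([ape::phylo]) and `clades` ([clade_map()]).
#' @export
example_study_tree <- function() {
  hydractinia <- c("Hydractinia_symbiolongicarpus", "Hydractinia_echinata")
  hydrozoa <- c(hydractinia, "Clytia_hemisphaerica", "Hydra_vulgaris",
                "Hydra_viridissima", "Podocoryna_carnea",
                "Turritopsis_dohrnii", "Craspedacusta_sowerbii")
  medusozoa <- c(hydrozoa, "Aurelia_aurita_pacific",
                 "Aurelia_aurita_atlantic", "Morbakka_virulenta")
  anthozoa <- c("Nematostella_vectensis", "Exaiptasia_diaphana",
                "Acropora_millepora", "Dendronephthya_gigantea")
  cnidaria <- c(medusozoa, anthozoa)
  bilateria <- c("Homo_sapiens", "Drosophila_melanogaster",
                 "Caenorhabditis_elegans", "Branchiostoma_floridae")
  outgroups <- c("Monosiga_brevicollis", "Capsaspora_owczarzaki",
                 "Saccharomyces_cerevisiae")
  nwk <- paste0(
    "(((((((((Hydractinia_symbiolongicarpus,Hydractinia_echinata)Hydractinia_mrca,",
    "Podocoryna_carnea)HydrPod,Clytia_hemisphaerica)HydrCly,",
    "(Turritopsis_dohrnii,Craspedacusta_sowerbii)OtherHydro)CoreHydro,",
    "(Hydra_vulgaris,Hydra_viridissima)Hydra)Hydrozoa_mrca,",
    "((Aurelia_aurita_pacific,Aurelia_aurita_atlantic)Aurelia,",
    "Morbakka_virulenta)Acraspeda)Medusozoa_mrca,",
    "((Nematostella_vectensis,Exaiptasia_diaphana)Actiniaria,",
    "(Acropora_millepora,Dendronephthya_gigantea)OtherAntho)Anthozoa_mrca)",
    "Cnidaria_mrca,((Homo_sapiens,Branchiostoma_floridae)Chordata,",
    "(Drosophila_melanogaster,Caenorhabditis_elegans)Ecdysozoa)Bilateria_mrca)",
    "Metazoa_mrca,(Monosiga_brevicollis,(Capsaspora_owczarzaki,",
    "Saccharomyces_cerevisiae)Opisthokonta_out)Outgroup_mrca)Root;"
  )
  tree <- label_internal_nodes(ape::read.tree(text = nwk))
  clades <- clade_map(
    sets = list(
      Metazoa = c(cnidaria, bilateria),
      Cnidaria = cnidaria,
      Medusozoa = medusozoa,
      Hydrozoa = hydrozoa,
      Anthozoa = anthozoa,
      Bilateria = bilateria,
      Hydractinia_Clytia = c(hydractinia, "Clytia_hemisphaerica",
                             "Podocoryna_carnea"),
      Hydractinia = hydractinia,
      Outgroups = outgroups
    ),
    roles = c(Metazoa = "metazoa", Cnidaria = "focal_phylum",
              Medusozoa = "", Hydrozoa = "", Anthozoa = "",
              Bilateria = "", Hydractinia_Clytia = "", Hydractinia = "",
              Outgroups = "outgroup")
  )
  list(tree = tree, clades = clades)
}
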