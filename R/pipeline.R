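# End-to-end orchestration: a single flat run configuration drives
# synthetic-data generation (or reading of real inputs), the specificity,
# marker, family-dynamics and macrosynteny stages, stage TSV outputs, a
# consolidated JSON summary and a log. Every output carries a hash of the
# configuration so files from different runs are distinguishable.

#' Build a run configuration
#'
#' @param seed integer seed for all randomness.
#' @param out_dir output directory (created if missing).
#' @param simulate logical: generate synthetic inputs (TRUE) or read the
#'   paths in `inputs`.
#' @param inputs named list of file paths (`orthogroups`, `tree`,
#'   `clades`, `markers`, `counts`, `positions_a`, `positions_b`) when
#'   `simulate = FALSE`.
#' @param stages character vector of stages to run, a subset of
#'   `c("specificity", "markers", "family_dynamics", "macrosynteny")`.
#' @param n_families,loss_prob,drift_prob simulator settings.
#' @param n_groups,translocation_rate,inversion_rate genome simulator
#'   settings.
#' @param fdr FDR level for scaffold-pair enrichment.
#' @param criteria marker [filter_criteria()].
#' @return list of class `run_config` with a `hash` element (md5 of the
#'   canonical JSON serialisation, excluding the hash itself).
#' @export
run_config <- function(seed = 1, out_dir = tempfile("orthoclades_run_"),
                       simulate = TRUE, inputs = list(),
                       stages = c("specificity", "markers",
                                  "family_dynamics", "macrosynteny"),
                       n_families = 2000, loss_prob = 0.05,
                       drift_prob = 0.3, n_groups = 5,
                       translocation_rate = 0.02, inversion_rate = 0.1,
                       fdr = 0.05, criteria = filter_criteria()) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              simulate = simulate, inputs = inputs, stages = stages,
              n_families = n_families, loss_prob = loss_prob,
              drift_prob = drift_prob, n_groups = n_groups,
              translocation_rate = translocation_rate,
              inversion_rate = inversion_rate, fdr = fdr,
              criteria = unclass(criteria))
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  cfg$hash <- NULL
  cfg$out_dir <- NULL  # the same analysis in another directory is the same run
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full pipeline
#'
#' Executes data generation/reading and the enabled analysis stages,
#' writes per-stage TSVs, a JSON summary and a log into the configured
#' output directory. Rerunning with the same configuration and inputs
#' reproduces identical outputs.
#'
#' @param cfg a [run_config()].
#' @return the report list (also written as `summary.json`), invisibly
#'   annotated with `paths`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(cfg$out_dir, "run.log"), open = "wt")
  on.exit(close(log_con))
  log_line(log_con, "run config hash ", cfg$hash)

  stage <- "data_io"
  result <- tryCatch({
    if (cfg$simulate) {
      ex <- example_study_tree()
      tree <- ex$tree
      clades <- ex$clades
      content <- simulate_gene_content(tree, n_families = cfg$n_families,
                                       loss_prob = cfg$loss_prob,
                                       drift_prob = cfg$drift_prob,
                                       seed = cfg$seed)
      og <- content$orthogroups
      counts <- content$counts
      log_line(log_con, "simulated ", length(og$og_id),
               " surviving families on ", length(tree$tip.label), " leaves")
    } else {
      req <- c("orthogroups", "tree", "clades")
      miss <- setdiff(req, names(cfg$inputs))
      if (length(miss) > 0) {
        stop("missing input path(s): ", paste(miss, collapse = ", "))
      }
      og <- read_orthogroups(cfg$inputs$orthogroups)
      tc <- read_tree_and_clades(cfg$inputs$tree, cfg$inputs$clades)
      tree <- tc$tree
      clades <- tc$clades
      content <- NULL
      counts <- if (!is.null(cfg$inputs$counts)) {
        read_family_counts(cfg$inputs$counts, tree)
      } else NULL
    }

    report <- list(config_hash = cfg$hash, seed = cfg$seed)

    stage <- "specificity"
    assignment <- classify_orthogroups(og, tree, clades)
    if ("specificity" %in% cfg$stages) {
      write_tsv_commented(specificity_table(assignment),
                          file.path(cfg$out_dir, "specificity.tsv"),
                          cfg$hash)
      report$confinement_fractions <- as.list(
        confinement_fractions(assignment))
      focal <- clades$sets[[clade_with_role(clades, "focal_phylum")]]
      g2og <- gene_to_og_map(og)
      cat_rows <- lapply(intersect(focal, og$species_order), function(sp) {
        genes <- names(g2og)[startsWith(names(g2og), paste0(sp, "|"))]
        if (cfg$simulate == FALSE) {
          genes <- unlist(lapply(og$membership, function(mm) mm[[sp]]),
                          use.names = FALSE)
        }
        if (length(genes) == 0) return(NULL)
        gc <- gene_categories(og, assignment, sp, genes, clades)
        data.frame(species = sp, t(gc$proportions),
                   stringsAsFactors = FALSE)
      })
      cat_df <- do.call(rbind, cat_rows)
      if (!is.null(cat_df)) {
        write_tsv_commented(cat_df,
                            file.path(cfg$out_dir, "gene_categories.tsv"),
                            cfg$hash)
        report$max_phylum_specific <- max(cat_df$phylum_specific)
      }
      log_line(log_con, "specificity: ", nrow(assignment$table),
               " orthogroups classified")
    }

    stage <- "family_dynamics"
    if ("family_dynamics" %in% cfg$stages && !is.null(counts)) {
      anc <- ancestral_counts(counts, tree)
      bct <- branch_changes(anc, tree)
      write_tsv_commented(bct, file.path(cfg$out_dir, "branch_changes.tsv"),
                          cfg$hash)
      welch <- terminal_vs_internal_test(bct)
      report$welch <- welch[c("mean_terminal", "mean_internal",
                              "t", "df", "p")]
      report$ancestral_provenance <- attr(anc, "provenance")
      log_line(log_con, "family dynamics: provenance ",
               attr(anc, "provenance"), ", Welch t = ",
               format(welch$t, digits = 5))
      cfg_pair <- intersect(c("Hydractinia_symbiolongicarpus",
                              "Hydractinia_echinata"), tree$tip.label)
      if (length(cfg_pair) == 2) {
        ps <- species_pair_summary(bct, anc, cfg_pair, tree,
                                   mrca_label(tree, cfg_pair))
        report$species_pair <- ps[c("fraction_changed", "genes_gained",
                                    "genes_lost", "gain_ratio",
                                    "loss_ratio", "n_lost_overlap")]
      }
    }

    stage <- "macrosynteny"
    if ("macrosynteny" %in% cfg$stages) {
      if (cfg$simulate) {
        pair <- c("Hydractinia_symbiolongicarpus", "Hydractinia_echinata")
        genomes <- simulate_genomes(content, pair, n_groups = cfg$n_groups,
                                    translocation_rate = cfg$translocation_rate,
                                    inversion_rate = cfg$inversion_rate,
                                    seed = cfg$seed)
        posA <- genomes$positions[[1]]
        posB <- genomes$positions[[2]]
      } else {
        posA <- read_gene_positions(cfg$inputs$positions_a, "gff3",
                                    species = "A")
        posB <- read_gene_positions(cfg$inputs$positions_b, "gff3",
                                    species = "B")
      }
      m <- shared_og_matrix(posA, posB, gene_to_og_map(og))
      tests <- test_scaffold_pairs(m, fdr = cfg$fdr)
      lg <- linkage_groups(tests, m)
      write_tsv_commented(tests, file.path(cfg$out_dir, "pair_tests.tsv"),
                          cfg$hash)
      write_tsv_commented(lg$groups,
                          file.path(cfg$out_dir, "linkage_groups.tsv"),
                          cfg$hash)
      write_tsv_commented(lg$dotplot,
                          file.path(cfg$out_dir, "dotplot.tsv"), cfg$hash)
      report$n_linkage_groups <- max(lg$groups$group)
      log_line(log_con, "macrosynteny: ", sum(tests$significant),
               " significant pairs, ", max(lg$groups$group), " groups")
    }

    stage <- "markers"
    if ("markers" %in% cfg$stages) {
      focal_sp <- "Hydractinia_symbiolongicarpus"
      ladder <- c("Hydractinia", "Hydractinia_Clytia", "Hydrozoa",
                  "Medusozoa", "Cnidaria", "Metazoa")
      if (cfg$simulate) {
        g2og <- gene_to_og_map(og)
        focal_genes <- names(g2og)[startsWith(names(g2og),
                                              paste0(focal_sp, "|"))]
        gc <- gene_categories(og, assignment, focal_sp, focal_genes,
                              clades)
        strata <- stats::setNames(gc$genes$category, gc$genes$gene)
        avail <- table(strata[strata != "unassigned"])
        avail <- avail[avail >= 25]
        # planted mixtures proportional to stratum availability, and a
        # cluster size well inside the pools, so every draw succeeds
        w <- as.vector(avail) / sum(avail)
        names(w) <- names(avail)
        n_per_cluster <- min(150L, floor(sum(avail) / 3))
        mixtures <- list()
        for (i in 1:3) mixtures[[paste0("C", i)]] <- w
        sim <- simulate_markers(strata, mixtures,
                                n_per_cluster = n_per_cluster,
                                seed = cfg$seed, criteria = cfg$criteria)
        markers <- sim$markers
      } else {
        markers <- read_markers(cfg$inputs$markers)
        g2og <- gene_to_og_map(og)
      }
      crit <- do.call(filter_criteria, cfg$criteria)
      kept <- filter_markers(markers, crit)
      ann <- assign_marker_categories(kept, assignment, ladder, g2og)
      grouping <- stats::setNames(unique(ann$cluster), unique(ann$cluster))
      prof <- group_profiles(ann, grouping)
      write_tsv_commented(prof, file.path(cfg$out_dir, "marker_profiles.tsv"),
                          cfg$hash)
      summ <- attr(prof, "summary")
      report$lineage_specific_fractions <- stats::setNames(
        as.list(summ$lineage_specific_fraction), summ$group)
      log_line(log_con, "markers: ", nrow(ann), " markers profiled in ",
               nrow(summ), " groups")
    }

    report
  }, error = function(e) {
    log_line(log_con, "ERROR in stage ", stage, ": ", conditionMessage(e))
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  write_report(result, file.path(cfg$out_dir, "summary.json"))
  log_line(log_con, "done")
  invisible(result)
}

#' Write the consolidated JSON report
#'
#' @param report named list of stage outputs (headline fractions, test
#'   results, counts).
#' @param path output JSON path.
#' @return the report, invisibly.
#' @export
write_report <- function(report, path) {
  if (length(report) == 0) stop("report needs at least one stage output")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(report)
}
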