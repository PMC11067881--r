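# Readers and writers for the external dialects the pipeline consumes:
# OrthoFinder Orthogroups.tsv, Newick + clade config, Seurat-style marker
# CSV/TSV, GFF3/BED gene positions, CAFE-style family count tables.
# Internal coordinates are 0-based half-open; conversion happens here,
# at the boundary, and nowhere else.

# ---------------------------------------------------------------------------
# OrthogroupTable

#' Construct an orthogroup table
#'
#' The central container for orthology-based analyses: a mapping
#' orthogroup -> species -> gene identifiers.
#'
#' @param og_id character vector of unique orthogroup identifiers.
#' @param membership list (one entry per orthogroup) of named lists
#'   (species -> character vector of gene ids; may be empty).
#' @param species_order character vector covering every species named in
#'   `membership`, in display order.
#' @return an object of class `orthogroup_table`.
#' @export
orthogroup_table <- function(og_id, membership, species_order) {
  og_id <- as.character(og_id)
  if (anyDuplicated(og_id)) {
    stop("duplicate orthogroup id: ",
         paste(unique(og_id[duplicated(og_id)]), collapse = ", "))
  }
  if (length(membership) != length(og_id)) {
    stop("membership must have one entry per orthogroup")
  }
  names(membership) <- og_id
  used_sp <- unique(unlist(lapply(membership, names), use.names = FALSE))
  extra <- setdiff(used_sp, species_order)
  if (length(extra) > 0) {
    stop("species_order does not cover: ", paste(extra, collapse = ", "))
  }
  genes <- unlist(membership, use.names = FALSE)
  if (anyDuplicated(genes)) {
    stop("gene assigned to more than one orthogroup: ",
         paste(unique(genes[duplicated(genes)])[1], collapse = ", "))
  }
  structure(
    list(og_id = og_id, membership = membership,
         species_order = as.character(species_order)),
    class = "orthogroup_table"
  )
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat("orthogroup_table:", length(x$og_id), "orthogroups,",
      length(x$species_order), "species,",
      length(unlist(x$membership, use.names = FALSE)), "genes\n")
  invisible(x)
}

#' Per-orthogroup gene counts
#'
#' @param table an [orthogroup_table()].
#' @return integer matrix, orthogroups x species.
#' @export
og_gene_counts <- function(table) {
  m <- vapply(table$species_order, function(sp) {
    vapply(table$membership, function(mm) {
      g <- mm[[sp]]
      if (is.null(g)) 0L else length(g)
    }, integer(1))
  }, integer(length(table$og_id)))
  m <- matrix(m, nrow = length(table$og_id),
              dimnames = list(table$og_id, table$species_order))
  m
}

#' Gene-to-orthogroup lookup
#'
#' @param table an [orthogroup_table()].
#' @return named character vector: gene id -> orthogroup id.
#' @export
gene_to_og_map <- function(table) {
  genes <- unlist(table$membership, use.names = FALSE)
  reps <- vapply(table$membership,
                 function(mm) length(unlist(mm, use.names = FALSE)),
                 integer(1))
  stats::setNames(rep(table$og_id, reps), genes)
}

#' Read an OrthoFinder-style Orthogroups.tsv file
#'
#' Tab-separated; first column is the orthogroup id, remaining columns are
#' species; cells hold comma(+space)-separated gene identifiers, empty cells
#' meaning "absent in this species".
#'
#' @param path file path.
#' @param dialect currently only `"orthofinder-tsv"`.
#' @return an [orthogroup_table()].
#' @export
read_orthogroups <- function(path, dialect = "orthofinder-tsv") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file: ", path)
  split_row <- function(x) {
    f <- strsplit(paste0(x, "\t\x01"), "\t", fixed = TRUE)[[1]]
    f[-length(f)]
  }
  header <- split_row(lines[1])
  species <- header[-1]
  ncol_expect <- length(header)
  body <- lines[-1]
  body <- body[body != ""]
  membership <- vector("list", length(body))
  og_id <- character(length(body))
  for (i in seq_along(body)) {
    f <- split_row(body[i])
    if (length(f) != ncol_expect) {
      stop("ragged row at line ", i + 1L, ": expected ", ncol_expect,
           " fields, found ", length(f))
    }
    og_id[i] <- trimws(f[1])
    cells <- lapply(f[-1], function(cell) {
      cell <- trimws(cell)
      if (cell == "") return(character(0))
      trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
    })
    names(cells) <- species
    membership[[i]] <- cells
  }
  orthogroup_table(og_id, membership, species)
}

#' Write an orthogroup table in the Orthogroups.tsv dialect
#'
#' @param table an [orthogroup_table()].
#' @param path output file path.
#' @export
write_orthogroups <- function(table, path) {
  header <- paste(c("Orthogroup", table$species_order), collapse = "\t")
  rows <- vapply(seq_along(table$og_id), function(i) {
    cells <- vapply(table$species_order, function(sp) {
      g <- table$membership[[i]][[sp]]
      if (is.null(g) || length(g) == 0) "" else paste(g, collapse = ", ")
    }, character(1))
    paste(c(table$og_id[i], cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SpeciesTree + CladeMap

#' Construct a clade map
#'
#' An ordered ladder of named clades (leaf-name sets), most inclusive first.
#' Clade sets must be nesting-consistent: pairwise disjoint or one containing
#' the other.
#'
#' @param sets named list of character vectors (clade name -> leaf names).
#' @param roles optional named character vector giving, per clade, one of
#'   `""`, `"focal_phylum"`, `"metazoa"`, `"outgroup"`.
#' @return an object of class `clade_map`.
#' @export
clade_map <- function(sets, roles = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("every clade needs a name")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0)) stop("empty clade set")
  nm <- names(sets)
  for (i in seq_along(sets)) {
    for (j in seq_len(i - 1L)) {
      a <- sets[[i]]; b <- sets[[j]]
      inter <- intersect(a, b)
      if (length(inter) > 0 && !all(a %in% b) && !all(b %in% a)) {
        stop("clades '", nm[j], "' and '", nm[i],
             "' partially overlap; clade sets must be nested or disjoint")
      }
    }
  }
  ord <- order(-lengths(sets), nm)
  sets <- sets[ord]
  if (is.null(roles)) roles <- stats::setNames(rep("", length(sets)), names(sets))
  roles <- roles[names(sets)]
  roles[is.na(roles)] <- ""
  names(roles) <- names(sets)
  structure(list(sets = sets, roles = roles), class = "clade_map")
}

#' @export
print.clade_map <- function(x, ...) {
  cat("clade_map:\n")
  for (nm in names(x$sets)) {
    cat(sprintf("  %-20s %3d species  %s\n", nm, length(x$sets[[nm]]),
                x$roles[[nm]]))
  }
  invisible(x)
}

# clade name carrying a given role, or NULL
clade_with_role <- function(clades, role) {
  hit <- names(clades$roles)[clades$roles == role]
  if (length(hit) == 0) NULL else hit[1]
}

#' Read a rooted species tree and its clade configuration
#'
#' The clade config is a tab-separated file with columns `clade`,
#' `species` (comma-separated leaf names) and optionally `role`
#' (`focal_phylum`, `metazoa`, `outgroup` or empty).
#'
#' @param newick path to a Newick file with a single rooted tree.
#' @param clade_config path to the clade config TSV.
#' @return list with elements `tree` (labelled [ape::phylo]) and
#'   `clades` ([clade_map()]).
#' @export
read_tree_and_clades <- function(newick, clade_config) {
  tree <- ape::read.tree(newick)
  if (is.null(tree)) stop("could not parse Newick: ", newick)
  tree <- label_internal_nodes(tree)
  cfg <- utils::read.delim(clade_config, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (!all(c("clade", "species") %in% names(cfg))) {
    stop("clade config needs columns 'clade' and 'species'")
  }
  sets <- lapply(strsplit(cfg$species, ",", fixed = TRUE), trimws)
  names(sets) <- cfg$clade
  bad <- lapply(sets, setdiff, y = tree$tip.label)
  offenders <- unique(unlist(bad))
  if (length(offenders) > 0) {
    stop("clade config names non-leaf species: ",
         paste(offenders, collapse = ", "))
  }
  roles <- if ("role" %in% names(cfg)) {
    stats::setNames(cfg$role, cfg$clade)
  } else NULL
  list(tree = tree, clades = clade_map(sets, roles))
}

#' Write a clade configuration TSV
#'
#' @param clades a [clade_map()].
#' @param path output path.
#' @export
write_clade_config <- function(clades, path) {
  df <- data.frame(
    clade = names(clades$sets),
    species = vapply(clades$sets, paste, character(1), collapse = ","),
    role = unname(clades$roles),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# MarkerTable

marker_columns <- c(gene = "gene", cluster = "cluster",
                    avg_log2FC = "avg_log2FC", p_val_adj = "p_val_adj",
                    pct_in = "pct.1", pct_out = "pct.2")

#' Read a Seurat-style per-cluster marker table
#'
#' Accepts CSV or TSV (decided by file extension). Rows whose numeric fields
#' do not parse, or fall outside their legal range (adjusted p and
#' expression fractions in \[0,1\]), are dropped with a reported count.
#'
#' @param path file path (.csv for comma-separated, anything else tab).
#' @param col_map named character vector mapping the internal fields
#'   `gene`, `cluster`, `avg_log2FC`, `p_val_adj`, `pct_in`, `pct_out` to
#'   the file's column names; defaults to the Seurat `FindAllMarkers`
#'   conventions (`pct.1`/`pct.2`).
#' @return data.frame of class `marker_table` with the six internal columns.
#' @export
read_markers <- function(path, col_map = marker_columns) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(col_map), names(raw))
  if (length(missing) > 0) {
    stop("marker table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- data.frame(
    gene = as.character(raw[[col_map[["gene"]]]]),
    cluster = as.character(raw[[col_map[["cluster"]]]]),
    avg_log2FC = suppressWarnings(as.numeric(raw[[col_map[["avg_log2FC"]]]])),
    p_val_adj = suppressWarnings(as.numeric(raw[[col_map[["p_val_adj"]]]])),
    pct_in = suppressWarnings(as.numeric(raw[[col_map[["pct_in"]]]])),
    pct_out = suppressWarnings(as.numeric(raw[[col_map[["pct_out"]]]])),
    stringsAsFactors = FALSE
  )
  ok <- !is.na(df$avg_log2FC) & !is.na(df$p_val_adj) &
    !is.na(df$pct_in) & !is.na(df$pct_out) &
    df$p_val_adj >= 0 & df$p_val_adj <= 1 &
    df$pct_in >= 0 & df$pct_in <= 1 & df$pct_out >= 0 & df$pct_out <= 1
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    message("read_markers: dropped ", n_drop,
            " row(s) with unparseable or out-of-range numeric fields")
  }
  df <- df[ok, , drop = FALSE]
  key <- paste(df$gene, df$cluster, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("gene", "cluster")][1, ]
    stop("duplicate (gene, cluster) pair: ", dup$gene, " / ", dup$cluster)
  }
  rownames(df) <- NULL
  class(df) <- c("marker_table", "data.frame")
  attr(df, "n_dropped") <- n_drop
  df
}

#' Write a marker table in the dialect [read_markers()] reads
#'
#' @param markers a `marker_table` data.frame.
#' @param path output path (.csv).
#' @export
write_markers <- function(markers, path) {
  out <- data.frame(
    gene = markers$gene, cluster = markers$cluster,
    avg_log2FC = markers$avg_log2FC, p_val_adj = markers$p_val_adj,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  out[["pct.1"]] <- markers$pct_in
  out[["pct.2"]] <- markers$pct_out
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GenePositionTable

new_gene_positions <- function(species, gene, scaffold, start, end, strand) {
  df <- data.frame(species = species, gene = gene, scaffold = scaffold,
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, stringsAsFactors = FALSE)
  key <- paste(df$species, df$gene, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (species, gene) pair: ",
         paste(df$gene[duplicated(key)][1]))
  }
  class(df) <- c("gene_positions", "data.frame")
  df
}

#' Read gene positions from GFF3 or BED
#'
#' GFF3 rows of type `gene` (1-based closed) and BED4+ rows (0-based
#' half-open) are both stored internally as 0-based half-open intervals.
#' Rows with an empty interval after conversion are rejected with a
#' reported count.
#'
#' @param path file path.
#' @param format `"gff3"` or `"bed"`.
#' @param species species name to stamp on every row (one species per file;
#'   see [read_gene_positions_multi()] for multi-file input).
#' @return data.frame of class `gene_positions` with columns
#'   `species`, `gene`, `scaffold`, `start`, `end`, `strand`.
#' @export
read_gene_positions <- function(path, format = c("gff3", "bed"), species) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    ids <- gr$ID
  } else {
    ids <- gr$name
  }
  if (is.null(ids) || any(is.na(ids))) {
    stop("gene identifiers missing in ", path)
  }
  # GRanges is 1-based closed for both formats; internal is 0-based half-open
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  ok <- start0 < end0
  if (any(!ok)) {
    message("read_gene_positions: rejected ", sum(!ok),
            " row(s) with empty intervals")
  }
  new_gene_positions(
    species = rep(species, sum(ok)),
    gene = as.character(ids)[ok],
    scaffold = as.character(GenomicRanges::seqnames(gr))[ok],
    start = start0[ok], end = end0[ok],
    strand = as.character(GenomicRanges::strand(gr))[ok]
  )
}

#' Read gene positions for several species at once
#'
#' @param files named character vector: species name -> file path.
#' @param format `"gff3"` or `"bed"`.
#' @return one combined `gene_positions` data.frame.
#' @export
read_gene_positions_multi <- function(files, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (is.null(names(files)) || any(names(files) == "")) {
    stop("files must be a named vector (species -> path)")
  }
  parts <- lapply(names(files), function(sp) {
    read_gene_positions(files[[sp]], format = format, species = sp)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("gene_positions", "data.frame")
  out
}

#' Write gene positions as GFF3
#'
#' Inverse of [read_gene_positions()]: internal 0-based half-open intervals
#' come out as 1-based closed `gene` features.
#'
#' @param pos a `gene_positions` data.frame (single species).
#' @param path output path.
#' @export
write_gene_positions <- function(pos, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = pos$scaffold,
    ranges = IRanges::IRanges(start = pos$start + 1L, end = pos$end),
    strand = ifelse(pos$strand %in% c("+", "-"), pos$strand, "*")
  )
  gr$type <- "gene"
  gr$ID <- pos$gene
  gr$source <- "orthoclades"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# ---------------------------------------------------------------------------
# FamilyCountsTable

#' Read a CAFE-style family count table
#'
#' Tab-separated; an optional `Description` column is ignored; the first
#' remaining column is the family id; every other column must name a node
#' of `tree` (leaves, and optionally internal nodes carrying precomputed
#' ancestral counts).
#'
#' @param path file path.
#' @param tree labelled rooted [ape::phylo] tree the columns resolve against.
#' @param dialect currently only `"cafe-tab"`.
#' @return integer matrix (families x nodes) of class `family_counts`, with
#'   attribute `has_internal` (logical).
#' @export
read_family_counts <- function(path, tree, dialect = "cafe-tab") {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  drop <- tolower(names(df)) %in% c("description", "desc")
  df <- df[, !drop, drop = FALSE]
  fam <- as.character(df[[1]])
  if (anyDuplicated(fam)) stop("duplicate family id")
  df <- df[, -1, drop = FALSE]
  labs <- all_node_labels(tree)
  unknown <- setdiff(names(df), labs)
  if (length(unknown) > 0) {
    stop("count column(s) matching no tree node: ",
         paste(unknown, collapse = ", "))
  }
  m <- as.matrix(df)
  mode(m) <- "numeric"
  if (any(is.na(m)) || any(m < 0) || any(m != floor(m))) {
    stop("family counts must be nonnegative integers")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- fam
  structure(m, class = c("family_counts", class(m)),
            has_internal = any(names(df) %in% tree$node.label))
}

#' Write a family count table in the CAFE tab dialect
#'
#' @param counts matrix (families x nodes), rownames = family ids.
#' @param path output path.
#' @export
write_family_counts <- function(counts, path) {
  df <- data.frame(Description = rep("(null)", nrow(counts)),
                   ID = rownames(counts), check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(unclass(counts)[, , drop = FALSE]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Commented TSV output used by the pipeline stages

write_tsv_commented <- function(df, path, config_hash = NULL) {
  hdr <- sprintf("# orthoclades %s%s",
                 as.character(utils::packageVersion("orthoclades")),
                 if (is.null(config_hash)) "" else paste0(" config=", config_hash))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
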