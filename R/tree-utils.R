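# Helpers over ape "phylo" trees. Node identifiers used throughout the
# package are character labels: tip labels for leaves, node labels for
# internal nodes (synthesised as N1..Nk when the Newick carries none).

#' Fill in missing internal-node labels of a rooted tree
#'
#' Internal nodes without a label get stable identifiers `N1`, `N2`, ...
#' (in ape node-number order). Errors if the resulting labels collide with
#' each other or with tip labels.
#'
#' @param tree an [ape::phylo] object, rooted.
#' @return the tree with a complete, unique `node.label` vector.
#' @export
label_internal_nodes <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  n_int <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n_int)
  empty <- is.na(lab) | lab == ""
  lab[empty] <- paste0("N", seq_len(n_int))[empty]
  all_lab <- c(tree$tip.label, lab)
  if (anyDuplicated(all_lab)) {
    stop("tree node labels are not unique: ",
         paste(unique(all_lab[duplicated(all_lab)]), collapse = ", "))
  }
  tree$node.label <- lab
  tree
}

# character labels for all nodes, indexed by ape node number
all_node_labels <- function(tree) c(tree$tip.label, tree$node.label)

# named list: node label -> character vector of descendant tip labels
# (a tip's set is itself)
node_tip_sets <- function(tree) {
  labs <- all_node_labels(tree)
  desc <- phangorn::Descendants(tree, seq_along(labs), type = "tips")
  sets <- lapply(desc, function(i) tree$tip.label[i])
  names(sets) <- labs
  sets
}

#' Most recent common ancestor of a set of leaves
#'
#' @param tree a labelled rooted [ape::phylo] tree.
#' @param tips character vector of tip labels (nonempty).
#' @return the node label of the MRCA; for a single tip, the tip itself.
#' @export
mrca_label <- function(tree, tips) {
  tips <- unique(tips)
  if (length(tips) == 0) stop("tips must be nonempty")
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing) > 0) {
    stop("species not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(tips) == 1) return(tips)
  all_node_labels(tree)[ape::getMRCA(tree, tips)]
}

#' Branch table of a rooted tree
#'
#' One row per branch, identified by its child node. The root has no row.
#'
#' @param tree a labelled rooted [ape::phylo] tree.
#' @return data.frame with columns `child`, `parent` (node labels) and
#'   `terminal` (logical: does the branch end in a leaf).
#' @export
branch_table <- function(tree) {
  labs <- all_node_labels(tree)
  data.frame(
    child = labs[tree$edge[, 2]],
    parent = labs[tree$edge[, 1]],
    terminal = tree$edge[, 2] <= length(tree$tip.label),
    stringsAsFactors = FALSE
  )
}

# ape node number from a label
node_number <- function(tree, label) {
  i <- match(label, all_node_labels(tree))
  if (is.na(i)) stop("unknown tree node: ", label)
  i
}
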