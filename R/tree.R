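#' Species tree with uniquely labeled branches
#'
#' A light wrapper around an [ape::phylo] object in which every node carries a
#' unique label. Branches are named after their child node, so the set of
#' branch ids is exactly the set of non-root node labels; the root itself has
#' no branch and no gain can be assigned to it except as a stem ("root") gain.
#'
#' @param phy An [ape::phylo] object. Internal nodes lacking labels are
#'   auto-labeled deterministically with their 0-based preorder index prefixed
#'   by "N" (the root, visited first, becomes "N0").
#' @return An object of class `species_tree`: a list with the labeled `phylo`
#'   in `$phy`, plus precomputed lookups (`$parent`, `$children`,
#'   `$branch_length` keyed by child-node label, `$leaves`, `$root`,
#'   `$preorder` -- node labels in preorder).
#' @export
as_species_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("`phy` must be an ape 'phylo' object")
  ntip <- length(phy$tip.label)
  if (ntip < 2) stop("tree must have at least 2 leaves")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (any(!nzchar(phy$tip.label))) stop("empty leaf label")
  if (is.null(phy$edge.length)) phy$edge.length <- rep(1, nrow(phy$edge))
  if (any(phy$edge.length < 0)) stop("negative branch length")

  phy <- stats::reorder(phy, "cladewise")
  nnode <- phy$Nnode
  root <- ntip + 1L
  preorder_nodes <- c(root, phy$edge[, 2])
  pre_idx <- match(seq_len(ntip + nnode), preorder_nodes) - 1L

  lab <- c(phy$tip.label,
           if (is.null(phy$node.label)) rep("", nnode) else phy$node.label)
  lab[is.na(lab)] <- ""
  fill <- which(!nzchar(lab))
  lab[fill] <- paste0("N", pre_idx[fill])
  if (anyDuplicated(lab))
    stop("duplicate node labels after auto-labeling: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  phy$node.label <- lab[(ntip + 1L):(ntip + nnode)]

  parent <- stats::setNames(lab[phy$edge[, 1]], lab[phy$edge[, 2]])
  children <- split(lab[phy$edge[, 2]], lab[phy$edge[, 1]])
  blen <- stats::setNames(phy$edge.length, lab[phy$edge[, 2]])

  structure(list(
    phy = phy,
    labels = lab,
    root = lab[root],
    leaves = phy$tip.label,
    parent = parent,
    children = children,
    branch_length = blen,
    preorder = lab[preorder_nodes]
  ), class = "species_tree")
}

#' Read a rooted species tree from a newick file
#'
#' @param path Path to a file containing a single newick tree. A trifurcating
#'   root is accepted and treated as a rooted multifurcation.
#' @return A [species_tree] object.
#' @export
read_species_tree <- function(path) {
  phy <- ape::read.tree(path)
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1) stop("file must contain exactly one tree")
    phy <- phy[[1]]
  }
  if (is.null(phy)) stop("could not parse a newick tree from ", path)
  as_species_tree(phy)
}

#' Write a species tree to a newick file
#'
#' @param tree A [species_tree].
#' @param path Output path.
#' @export
write_species_tree <- function(tree, path) {
  stopifnot(inherits(tree, "species_tree"))
  ape::write.tree(tree$phy, file = path)
  invisible(path)
}

#' Branch ids of a species tree
#'
#' Branches are named by their child node; the root has no branch.
#' @param tree A [species_tree].
#' @return Character vector of branch ids (all non-root node labels).
#' @export
tree_branches <- function(tree) setdiff(tree$labels, tree$root)

#' Leaf (taxon) labels of a species tree
#' @param tree A [species_tree].
#' @export
tree_leaves <- function(tree) tree$leaves

#' Labels on the path from a node to the root
#'
#' @param tree A [species_tree].
#' @param label A node label.
#' @param include_self Include `label` itself? Default TRUE.
#' @return Character vector of labels from `label` up to and including the
#'   root.
#' @export
root_path <- function(tree, label, include_self = TRUE) {
  if (!label %in% tree$labels) stop("unknown node label: ", label)
  path <- character(0)
  cur <- label
  repeat {
    path <- c(path, cur)
    if (cur == tree$root) break
    cur <- tree$parent[[cur]]
  }
  if (!include_self) path <- path[-1]
  path
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree:", length(x$leaves), "leaves,",
      length(x$labels) - length(x$leaves), "internal nodes\n")
  cat("Root:", x$root, " Branches:", length(x$labels) - 1L, "\n")
  invisible(x)
}
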