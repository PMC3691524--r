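#' Read a rooted binary tree from a Newick file
#'
#' The parsimony machinery requires a rooted, strictly binary tree.
#' Multifurcating input is rejected by default; with `binarize = TRUE`
#' each multifurcation is resolved deterministically
#' (`ape::multi2di(random = FALSE)`) into a caterpillar of zero-length
#' branches.  Silent binarization is avoided because it changes
#' parsimony counts without the user's knowledge.
#'
#' @param path path to a Newick file (or a Newick string containing
#'   `"("` and `";"`).
#' @param binarize resolve multifurcations instead of rejecting them.
#' @return an `ape::phylo` tree, rooted and binary.
#' @export
read_newick <- function(path, binarize = FALSE) {
  tr <- if (grepl("\\(", path) && grepl(";", path))
    ape::read.tree(text = path)
  else {
    if (!file.exists(path)) stop("file not found: ", path)
    ape::read.tree(path)
  }
  if (is.null(tr)) stop("could not parse Newick input")
  check_binary_rooted(tr, binarize = binarize)
}

check_binary_rooted <- function(tr, binarize = FALSE) {
  if (!ape::is.binary(tr) || !ape::is.rooted(tr)) {
    if (!binarize) {
      deg <- tabulate(tr$edge[, 1],
                      nbins = tr$Nnode + length(tr$tip.label))
      bad <- which(deg > 2L)
      stop("tree is not binary and rooted",
           if (length(bad)) paste0(" (node ", bad[1L], " has ",
                                   deg[bad[1L]], " children)") else "",
           "; pass binarize = TRUE to resolve deterministically")
    }
    tr <- ape::multi2di(tr, random = FALSE)
    if (!is.null(tr$edge.length))
      tr$edge.length[is.na(tr$edge.length)] <- 0
    if (!ape::is.binary(tr) || !ape::is.rooted(tr))
      stop("could not resolve tree into a rooted binary tree")
  }
  tr
}

#' Validate a tree against an alignment
#'
#' Checks that the tree is rooted and binary and that its leaf labels
#' are exactly the alignment's sequence names, and attaches the
#' leaf-to-row mapping used by the parsimony pass.
#'
#' @param tree an `ape::phylo` tree.
#' @param aln an [rna_alignment].
#' @param binarize resolve multifurcations instead of rejecting them.
#' @return the tree, with attribute `row_of_tip` (alignment row index of
#'   each tip, in tip order).
#' @export
validate_tree <- function(tree, aln, binarize = FALSE) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "rna_alignment"))
  tree <- check_binary_rooted(tree, binarize = binarize)
  extra <- setdiff(tree$tip.label, aln$names)
  missing <- setdiff(aln$names, tree$tip.label)
  if (length(extra) || length(missing))
    stop("tree/alignment name mismatch;",
         if (length(extra)) paste0(" only in tree: ",
                                   paste(extra, collapse = ", ")) else "",
         if (length(missing)) paste0(" only in alignment: ",
                                     paste(missing, collapse = ", "))
         else "")
  attr(tree, "row_of_tip") <- match(tree$tip.label, aln$names)
  tree
}

# Postorder traversal bookkeeping for a rooted binary phylo tree:
# child matrix (2 x nnode over internal node ids) and the internal nodes
# in postorder (children before parents).
tree_topology <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  kids <- matrix(0L, nrow = 2L, ncol = ntip + nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    if (kids[1L, p] == 0L) kids[1L, p] <- tree$edge[e, 2]
    else if (kids[2L, p] == 0L) kids[2L, p] <- tree$edge[e, 2]
    else stop("node ", p, " has more than 2 children")
  }
  internal <- which(kids[1L, ] != 0L)
  if (any(kids[2L, internal] == 0L))
    stop("node ", internal[kids[2L, internal] == 0L][1L],
         " has a single child; tree is not strictly binary")
  po <- ape::reorder.phylo(tree, "postorder")
  order_internal <- unique(po$edge[, 1])  # postorder: children first
  list(ntip = ntip, nnode = nnode, kids = kids,
       internal = order_internal, root = ntip + 1L)
}
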