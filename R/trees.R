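#' Read and validate a phylogenetic tree
#'
#' Parses a newick string or file into an unrooted `ape::phylo` tree suitable
#' for codon-model likelihood evaluation.  Branch lengths are expected
#' substitutions per codon; missing lengths default to `default_blen`.
#' Multifurcations are resolved arbitrarily with zero-length edges (with a
#' warning); a root of degree two is removed by unrooting.
#'
#' @param newick newick text (starting with `(`) or a file path.
#' @param taxa optional character vector; every leaf label must belong to it.
#' @param default_blen branch length used where the newick omits one.
#' @return an unrooted `phylo` object.
#' @export
read_phylo_tree <- function(newick, taxa = NULL, default_blen = 0.1) {
  tr <- if (grepl("^\\s*\\(", newick[1])) {
    ape::read.tree(text = newick)
  } else {
    ape::read.tree(newick)
  }
  if (is.null(tr)) stop("could not parse newick input")
  if (!is.null(taxa)) {
    unknown <- setdiff(tr$tip.label, taxa)
    if (length(unknown)) {
      stop("tree leaf label(s) not in alignment: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (length(tr$tip.label) > 2) {
    if (!ape::is.binary(tr)) {
      warning("non-binary tree resolved arbitrarily with zero-length edges")
      tr <- ape::multi2di(tr, random = FALSE)
      if (!is.null(tr$edge.length)) tr$edge.length[is.na(tr$edge.length)] <- 0
    }
    if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  }
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(default_blen, nrow(tr$edge))
  }
  tr$edge.length[is.na(tr$edge.length)] <- default_blen
  if (any(tr$edge.length < 0)) stop("negative branch lengths are not allowed")
  tr
}

#' Flag foreground edges for branch-site analysis
#'
#' Marks the terminal branch leading to each named taxon (or, for a vector
#' of length > 1 with `mrca = TRUE`, the stem branch of their most recent
#' common ancestor) as foreground for branch-site Model A.
#'
#' @param tree a `phylo` tree.
#' @param taxon character vector of tip labels.
#' @param mrca if `TRUE` and several taxa are given, flag the stem edge of
#'   their MRCA instead of the terminal edges.
#' @return the tree with an integer attribute-style element `foreground`
#'   holding row indices into `tree$edge`.
#' @export
set_foreground <- function(tree, taxon, mrca = FALSE) {
  if (length(taxon) == 0) stop("foreground taxon set must not be empty")
  missing_tax <- setdiff(taxon, tree$tip.label)
  if (length(missing_tax)) {
    stop("foreground taxon not in tree: ", paste(missing_tax, collapse = ", "))
  }
  if (mrca && length(taxon) > 1) {
    node <- ape::getMRCA(tree, taxon)
    idx <- which(tree$edge[, 2] == node)
  } else {
    tips <- match(taxon, tree$tip.label)
    idx <- which(tree$edge[, 2] %in% tips)
  }
  if (length(idx) == 0) stop("could not locate foreground edge(s)")
  tree$foreground <- as.integer(idx)
  tree
}

# Postorder traversal data shared by likelihood and simulation code.
tree_prune_data <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  root <- tr$edge[nrow(tr$edge), 1]
  fg <- integer(0)
  if (!is.null(tree$foreground)) {
    # foreground indices refer to the original edge order; remap by (par,chd)
    key0 <- paste(tree$edge[, 1], tree$edge[, 2])
    key1 <- paste(tr$edge[, 1], tr$edge[, 2])
    fg <- match(key0[tree$foreground], key1)
  }
  list(tree = tr, edge = tr$edge, blen = tr$edge.length, ntip = ntip,
       nnode = ntip + tr$Nnode, root = root, foreground = fg)
}
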