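#' Reference trees
#'
#' A `reference_tree` is a rooted, fully bifurcating tree over the study taxa.
#' Leaves are contemporary taxa (languages, genomes); internal nodes are
#' hypothetical taxonomic units (HTUs), i.e. ancestral taxa. The object wraps
#' an [ape::phylo] tree and precomputes the traversal structures the
#' origin-loss algorithms need: parent/child links, a post-order node
#' sequence, and the descendant-leaf set of every node.
#'
#' Polytomies in the input are resolved deterministically in input child
#' order ([ape::multi2di] with `random = FALSE`), so a tree with `n` leaves
#' always has `2n - 1` nodes. Node indices follow the `phylo` convention:
#' leaves `1..n`, internal nodes `n+1 .. 2n-1` with the root at `n+1`.
#' Internal nodes without a (unique, non-empty) label in the input receive a
#' stable identifier `HTU<k>` where `k` is the node's post-order index.
#'
#' @param phy An [ape::phylo] object (rooted, >= 2 leaves).
#' @return An object of class `reference_tree`: a list with elements
#'   `phylo`, `n_leaf`, `n_node`, `root`, `parent` (integer, 0 at the root),
#'   `kid1`/`kid2` (child indices, 0 at leaves), `is_leaf`, `labels`
#'   (node identifiers, leaf labels first), `postorder` (node indices,
#'   children before parents) and `leaf_desc` (list of descendant leaf
#'   indices per node).
#' @examples
#' tr <- read_newick(textConnection("((A,B),(C,D));"))
#' tr$n_node # 7
#' @export
as_reference_tree <- function(phy) {
  if (inherits(phy, "reference_tree")) {
    return(phy)
  }
  if (!inherits(phy, "phylo")) {
    abort("`phy` must be an ape 'phylo' object")
  }
  if (length(phy$tip.label) < 2) {
    abort("reference tree must have at least 2 leaves")
  }
  phy <- suppressWarnings(ape::collapse.singles(phy))
  n <- length(phy$tip.label)
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup) > 0) {
    abort(paste0("duplicate leaf label(s): ", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(phy$tip.label))) {
    abort("leaf labels must be non-empty")
  }
  # a basal multifurcation is treated as a polytomy of a rooted tree and
  # resolved deterministically in input child order
  if (!ape::is.binary(phy)) {
    phy <- ape::multi2di(phy, random = FALSE)
  }
  if (!ape::is.rooted(phy)) {
    abort("reference tree must be rooted")
  }

  n_node <- 2L * n - 1L
  parent <- integer(n_node)
  kid1 <- integer(n_node)
  kid2 <- integer(n_node)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]
    v <- phy$edge[e, 2L]
    parent[v] <- p
    if (kid1[p] == 0L) kid1[p] <- v else kid2[p] <- v
  }
  root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])
  if (length(root) != 1L) {
    abort("tree does not have a unique root")
  }
  root <- as.integer(root)
  is_leaf <- seq_len(n_node) <= n

  # iterative DFS -> reverse gives a post-order (children before parents)
  s1 <- root
  s2 <- integer(0)
  while (length(s1) > 0) {
    v <- s1[length(s1)]
    s1 <- s1[-length(s1)]
    s2 <- c(s2, v)
    if (!is_leaf[v]) s1 <- c(s1, kid1[v], kid2[v])
  }
  postorder <- rev(s2)

  leaf_desc <- vector("list", n_node)
  for (v in postorder) {
    leaf_desc[[v]] <- if (is_leaf[v]) v else c(leaf_desc[[kid1[v]]], leaf_desc[[kid2[v]]])
  }

  labels <- character(n_node)
  labels[seq_len(n)] <- phy$tip.label
  given <- phy$node.label
  post_index <- match(seq_len(n_node), postorder)
  for (v in (n + 1L):n_node) {
    lab <- if (!is.null(given)) given[v - n] else ""
    if (is.null(lab) || is.na(lab) || !nzchar(lab)) {
      lab <- sprintf("HTU%d", post_index[v])
    }
    labels[v] <- lab
  }
  if (anyDuplicated(labels)) {
    # fall back to structural ids for all internal nodes
    labels[(n + 1L):n_node] <- sprintf("HTU%d", post_index[(n + 1L):n_node])
  }
  phy$node.label <- labels[(n + 1L):n_node]

  structure(
    list(
      phylo = phy, n_leaf = n, n_node = n_node, root = root,
      parent = parent, kid1 = kid1, kid2 = kid2, is_leaf = is_leaf,
      labels = labels, postorder = postorder, leaf_desc = leaf_desc
    ),
    class = "reference_tree"
  )
}

#' @export
print.reference_tree <- function(x, ...) {
  cat(sprintf(
    "<reference_tree: %d leaves, %d nodes (%d internal), root = %s>\n",
    x$n_leaf, x$n_node, x$n_node - x$n_leaf, x$labels[x$root]
  ))
  invisible(x)
}

#' Taxon names of a reference tree
#' @param tree A [reference_tree][as_reference_tree].
#' @return Character vector of leaf labels (contemporary taxa).
#' @export
taxa <- function(tree) {
  tree$labels[seq_len(tree$n_leaf)]
}

#' Map taxon labels to leaf indices
#' @noRd
leaf_index <- function(tree, labels) {
  idx <- match(labels, tree$labels[seq_len(tree$n_leaf)])
  if (anyNA(idx)) {
    abort(paste0(
      "unknown taxon label(s): ",
      paste(labels[is.na(idx)], collapse = ", ")
    ))
  }
  idx
}

#' Most recent common ancestor
#'
#' Finds the lowest node of the tree whose descendant leaves contain all the
#' query taxa. For a single taxon the MRCA is the leaf itself.
#'
#' @param tree A [reference_tree][as_reference_tree].
#' @param leaves Taxon labels (character) or leaf indices (integer).
#' @return The MRCA node index.
#' @examples
#' tr <- read_newick(textConnection("((A,B),(C,D));"))
#' mrca(tr, c("A", "B")) # the cherry parent
#' @export
mrca <- function(tree, leaves) {
  if (is.character(leaves)) leaves <- leaf_index(tree, leaves)
  leaves <- unique(as.integer(leaves))
  if (length(leaves) == 0) abort("`leaves` must be non-empty")
  if (any(leaves < 1L | leaves > tree$n_leaf)) abort("leaf index out of range")
  v <- leaves[1L]
  while (!all(leaves %in% tree$leaf_desc[[v]])) {
    v <- tree$parent[v]
  }
  v
}

#' All node indices in the subtree rooted at `v` (including `v`)
#' @noRd
subtree_nodes <- function(tree, v) {
  out <- integer(0)
  stack <- v
  while (length(stack) > 0) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, u)
    if (!tree$is_leaf[u]) stack <- c(stack, tree$kid1[u], tree$kid2[u])
  }
  out
}

#' Per-node count of present descendant leaves for one character row
#' @noRd
presence_counts <- function(tree, present) {
  cnt <- integer(tree$n_node)
  cnt[seq_len(tree$n_leaf)] <- as.integer(present)
  for (v in tree$postorder) {
    if (!tree$is_leaf[v]) cnt[v] <- cnt[tree$kid1[v]] + cnt[tree$kid2[v]]
  }
  cnt
}

#' Clade membership test: is `b` inside the subtree rooted at `a`?
#' @noRd
is_descendant <- function(tree, a, b) {
  v <- b
  repeat {
    if (v == a) return(TRUE)
    if (v == tree$root) return(FALSE)
    v <- tree$parent[v]
  }
}
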