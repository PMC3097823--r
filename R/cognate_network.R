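#' Shared-character matrix between taxa
#'
#' Builds the symmetric taxa-by-taxa matrix whose off-diagonal entry
#' `a[i, j]` counts the characters present in both taxa, and whose diagonal
#' holds each taxon's inventory size. This is the weighted adjacency matrix
#' of the shared-character network.
#'
#' @param pap A binary PAP matrix (characters x taxa).
#' @return An integer matrix of class `shared_matrix`.
#' @export
shared_matrix <- function(pap) {
  if (nrow(pap) > 0) pap <- validate_pap(pap)
  m <- crossprod(pap)
  storage.mode(m) <- "integer"
  class(m) <- c("shared_matrix", class(m))
  m
}

#' Summary of distinct presence/absence patterns
#'
#' @param pap A binary PAP matrix.
#' @return A one-row tibble: `n_characters`, `n_distinct` (distinct 0/1 row
#'   vectors), `n_unique` (patterns seen exactly once), `n_recurring`
#'   (patterns seen more than once).
#' @export
pap_summary <- function(pap) {
  pap <- validate_pap(pap)
  key <- apply(pap, 1L, paste0, collapse = "")
  tab <- table(key)
  tibble(
    n_characters = nrow(pap),
    n_distinct = length(tab),
    n_unique = sum(tab == 1L),
    n_recurring = sum(tab > 1L)
  )
}

#' Congruence of a presence pattern with the reference tree
#'
#' A pattern is congruent when its present-leaf set is exactly the leaf set
#' of one clade of the tree, i.e. a single origin with zero losses explains
#' it. `congruence()` applies the test to every row of a PAP matrix.
#'
#' @param tree A [reference_tree][as_reference_tree].
#' @param pap_row Binary presence vector (named by taxon or in leaf order).
#' @return `is_congruent()`: a logical scalar. `congruence()`: a named
#'   logical vector over characters.
#' @export
is_congruent <- function(tree, pap_row) {
  tree <- as_reference_tree(tree)
  pres <- row_presence(tree, pap_row)
  cnt <- presence_counts(tree, pres)
  origin <- descend_mrca(tree, tree$root, cnt)
  cnt[origin] == length(tree$leaf_desc[[origin]])
}

#' @rdname is_congruent
#' @param pap A binary PAP matrix.
#' @export
congruence <- function(tree, pap) {
  tree <- as_reference_tree(tree)
  pap <- validate_pap(pap)
  idx <- match(tree$labels[seq_len(tree$n_leaf)], colnames(pap))
  if (anyNA(idx)) abort("PAP taxa do not cover the tree's leaf labels")
  pap <- pap[, idx, drop = FALSE]
  setNames(
    vapply(seq_len(nrow(pap)), function(i) is_congruent(tree, pap[i, ]), logical(1)),
    rownames(pap)
  )
}

#' Coerce adjacency input to a dense symmetric matrix with zero diagonal
#' @noRd
as_adjacency <- function(adj) {
  if (inherits(adj, "igraph")) {
    adj <- as.matrix(igraph::as_adjacency_matrix(adj, attr = if ("weight" %in% igraph::edge_attr_names(adj)) "weight" else NULL))
  }
  A <- as.matrix(adj)
  mode(A) <- "numeric"
  if (nrow(A) != ncol(A) || any(abs(A - t(A)) > 1e-9)) {
    abort("adjacency must be a symmetric square matrix")
  }
  if (any(A < 0)) abort("adjacency weights must be non-negative")
  diag(A) <- 0
  A
}

#' Weighted modularity of a network partition
#'
#' `Q = sum_c [ W_c / W - (S_c / 2W)^2 ]` where `W` is the total edge
#' weight, `W_c` the weight inside community `c` and `S_c` the summed
#' weighted degree of its members. Diagonal entries (self-sharing) are
#' excluded. With every node in one community, `Q = 0`.
#'
#' @param adj Symmetric non-negative adjacency matrix (or igraph graph).
#' @param membership Community id per node.
#' @return Modularity score `Q`.
#' @export
modularity_q <- function(adj, membership) {
  A <- as_adjacency(adj)
  if (length(membership) != nrow(A)) abort("membership length must match adjacency")
  W2 <- sum(A) # = 2W
  if (W2 <= 0) abort("graph has no edge weight")
  k <- rowSums(A)
  q <- 0
  for (cc in unique(membership)) {
    idx <- membership == cc
    q <- q + sum(A[idx, idx]) / W2 - (sum(k[idx]) / W2)^2
  }
  q
}

#' Community detection by the leading eigenvector of the modularity matrix
#'
#' Recursive spectral bisection: each group is split by the sign of the
#' leading eigenvector of its generalized (weighted) modularity matrix, and
#' a split is kept only while it increases the modularity of the whole
#' network. Groups whose leading eigenvalue is non-positive, or whose best
#' split does not improve modularity, are indivisible and become final
#' modules. Disconnected components are handled separately. Eigenvector
#' entries equal to zero are assigned to the positive side, and the dense
#' symmetric eigensolver makes the procedure deterministic. No
#' Kernighan-Lin refinement sweep is applied.
#'
#' @param adj Symmetric non-negative adjacency matrix (or igraph graph);
#'   row/column names become taxon names.
#' @return A `community_partition`: list with `membership` (named integer
#'   vector), `n_modules` and modularity `q`.
#' @export
leading_eigenvector_communities <- function(adj) {
  A <- as_adjacency(adj)
  n <- nrow(A)
  W2 <- sum(A)
  if (W2 <= 0) abort("graph has no edge weight")
  k <- rowSums(A)
  B <- A - outer(k, k) / W2
  tol <- 1e-10

  membership <- integer(n)
  next_id <- 0L
  assign_module <- function(idx) {
    next_id <<- next_id + 1L
    membership[idx] <<- next_id
  }
  split_group <- function(idx) {
    if (length(idx) == 1L) {
      assign_module(idx)
      return(invisible())
    }
    Bg <- B[idx, idx, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    e <- eigen(Bg, symmetric = TRUE)
    if (e$values[1L] <= tol) {
      assign_module(idx)
      return(invisible())
    }
    u <- e$vectors[, 1L]
    s <- ifelse(u >= 0, 1, -1)
    dq <- sum(s * (Bg %*% s)) / (2 * W2)
    if (dq <= tol || all(s > 0) || all(s < 0)) {
      assign_module(idx)
      return(invisible())
    }
    split_group(idx[s > 0])
    split_group(idx[s < 0])
  }

  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  )$membership
  for (cc in sort(unique(comp))) {
    split_group(which(comp == cc))
  }
  names(membership) <- rownames(A) %||% as.character(seq_len(n))
  structure(
    list(
      membership = membership,
      n_modules = length(unique(membership)),
      q = modularity_q(A, membership)
    ),
    class = "community_partition"
  )
}

#' @importFrom rlang %||%
NULL

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf(
    "<community_partition: %d modules, Q = %.4f>\n", x$n_modules, x$q
  ))
  invisible(x)
}
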