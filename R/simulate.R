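#' Simulate gain-loss-borrowing evolution of binary characters
#'
#' Each character originates at one node drawn uniformly over the
#' ancestral (internal) nodes, is inherited down the tree with an
#' independent per-branch loss probability `q`, and receives
#' `Poisson(lambda)` borrowing events. Each borrowing copies the character
#' to a uniformly chosen node not currently carrying it — internal
#' recipients model ancient transfers, leaf recipients recent ones — and
#' presence then propagates down from the recipient under the same loss
#' process. Characters absent from every leaf are redrawn, since all-zero
#' patterns are unobservable. All events are logged as ground truth.
#'
#' Restricting origins to ancestral nodes is what makes the emitted data
#' uniformitarian at `lambda = 0`: characters are innovations of ancestral
#' lineages that descend vertically, so ancestral and contemporary
#' inventory sizes are exchangeable and the model-selection criterion is
#' meaningful. With `origin_pool = "all"`, origins may also land on
#' leaves; the resulting leaf-private characters systematically inflate
#' contemporary inventories, which is useful for studying how the
#' criterion behaves on non-uniformitarian data.
#'
#' @param tree A [reference_tree][as_reference_tree].
#' @param n_characters Number of characters to emit (default 500).
#' @param q Per-branch loss probability in `[0, 1)` (default 0.05).
#' @param lambda Mean borrowing events per character (default 0.6).
#' @param seed Optional integer seed; when given, the run is fully
#'   reproducible.
#' @param origin_pool `"internal"` (default) draws true origins uniformly
#'   over ancestral nodes; `"all"` draws them over all nodes including
#'   leaves.
#' @return A list with `pap` (binary matrix, characters x taxa) and
#'   `truth`, a tibble per character: `character`, `origin` (node index),
#'   `losses` (list of child nodes whose incoming branch lost the
#'   character), `borrowings` (list of recipient nodes),
#'   `n_borrowings`, and the run parameters as attributes.
#' @export
simulate_pap <- function(tree, n_characters = 500, q = 0.05, lambda = 0.6,
                         seed = NULL, origin_pool = c("internal", "all")) {
  tree <- as_reference_tree(tree)
  origin_pool <- match.arg(origin_pool)
  if (q < 0 || q >= 1) abort("`q` must be in [0, 1)")
  if (lambda < 0) abort("`lambda` must be >= 0")
  if (n_characters < 1) abort("`n_characters` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pool <- if (origin_pool == "internal") which(!tree$is_leaf) else seq_len(tree$n_node)

  propagate_down <- function(pres, from, losses) {
    # copy presence into the subtree below `from`, losing each branch w.p. q;
    # subtrees already carrying the character are left to their own history
    stack <- from
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (tree$is_leaf[v]) next
      for (ch in c(tree$kid1[v], tree$kid2[v])) {
        if (pres[ch]) next
        if (stats::runif(1) >= q) {
          pres[ch] <- TRUE
          stack <- c(stack, ch)
        } else {
          losses <- c(losses, ch)
        }
      }
    }
    list(pres = pres, losses = losses)
  }

  pap <- matrix(0L, nrow = n_characters, ncol = tree$n_leaf,
                dimnames = list(sprintf("char%04d", seq_len(n_characters)),
                                tree$labels[seq_len(tree$n_leaf)]))
  origin <- integer(n_characters)
  losses <- vector("list", n_characters)
  borrowings <- vector("list", n_characters)
  for (i in seq_len(n_characters)) {
    repeat {
      pres <- logical(tree$n_node)
      o <- pool[sample.int(length(pool), 1L)]
      pres[o] <- TRUE
      st <- propagate_down(pres, o, integer(0))
      pres <- st$pres
      ls <- st$losses
      bw <- integer(0)
      nb <- stats::rpois(1L, lambda)
      if (nb > 0) {
        for (b in seq_len(nb)) {
          cand <- which(!pres)
          if (length(cand) == 0) break
          r <- cand[sample.int(length(cand), 1L)]
          pres[r] <- TRUE
          bw <- c(bw, r)
          st <- propagate_down(pres, r, ls)
          pres <- st$pres
          ls <- st$losses
        }
      }
      if (any(pres[seq_len(tree$n_leaf)])) break
    }
    pap[i, ] <- as.integer(pres[seq_len(tree$n_leaf)])
    origin[i] <- o
    losses[[i]] <- sort(unique(ls))
    borrowings[[i]] <- bw
  }
  truth <- tibble(
    character = rownames(pap),
    origin = origin,
    losses = losses,
    borrowings = borrowings,
    n_borrowings = vapply(borrowings, length, integer(1))
  )
  attr(truth, "q") <- q
  attr(truth, "lambda") <- lambda
  attr(truth, "seed") <- seed
  attr(truth, "origin_pool") <- origin_pool
  list(pap = pap, truth = truth)
}

#' Reinsert known borrowings into a PAP matrix
#'
#' Sets the listed (character, taxon) cells to 1 (idempotent for cells
#' already present). Used to emulate datasets where attested borrowings
#' are coded back into their characters so detection can be validated
#' with [validate_known_borrowings].
#'
#' @param pap A binary PAP matrix.
#' @param known Data frame with columns `character` and `taxon`.
#' @return The modified PAP matrix, with `known` recorded in
#'   `attr(, "reinserted")`.
#' @export
reinsert_borrowings <- function(pap, known) {
  known <- tibble::as_tibble(known)
  if (!all(c("character", "taxon") %in% names(known))) {
    abort("`known` needs columns character and taxon")
  }
  ri <- match(known$character, rownames(pap))
  cj <- match(as.character(known$taxon), colnames(pap))
  if (anyNA(ri) || anyNA(cj)) {
    abort("unknown character or taxon in reinsertion list")
  }
  pap[cbind(ri, cj)] <- 1L
  attr(pap, "reinserted") <- known
  pap
}

#' Randomize the leaf labels of a tree
#'
#' Permutes the leaf labels uniformly at random while keeping the topology
#' fixed. Analyses repeated on label-randomized trees serve as a
#' robustness control: with the vertical signal destroyed, far more
#' borrowing is needed to explain the same patterns.
#'
#' @param tree A [reference_tree][as_reference_tree].
#' @param seed Optional integer seed.
#' @return A new `reference_tree` with permuted leaf labels.
#' @export
randomize_tree_labels <- function(tree, seed = NULL) {
  tree <- as_reference_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  phy <- tree$phylo
  phy$tip.label <- sample(phy$tip.label)
  as_reference_tree(phy)
}

#' Random rooted binary reference tree
#'
#' Convenience wrapper around [ape::rtree] for simulation studies.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param seed Optional integer seed.
#' @return A `reference_tree` with leaves `t1 .. tn`.
#' @export
random_reference_tree <- function(n_leaves, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as_reference_tree(ape::rtree(n_leaves, rooted = TRUE))
}
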