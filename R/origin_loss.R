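#' Borrowing-allowance model specifications
#'
#' The bounded-origin parsimony models place between 1 and 16 origins per
#' character on the reference tree:
#' * `LO` (loss only): one origin, forced at the root; every character is
#'   ancestral and patchy distributions are explained purely by loss.
#' * `SO` (single origin): one origin at the MRCA of the present taxa.
#' * `BOR1`, `BOR3`, `BOR7`, `BOR15`: up to 2, 4, 8 or 16 origins; the
#'   first origin is "the" origin, every additional one is a borrowing.
#'
#' @param name Model name, one of `"LO"`, `"SO"`, `"BOR1"`, `"BOR3"`,
#'   `"BOR7"`, `"BOR15"`.
#' @return A list with `name`, `max_origins` and `root_forced`.
#' @export
model_spec <- function(name) {
  specs <- list(
    LO = list(name = "LO", max_origins = 1L, root_forced = TRUE),
    SO = list(name = "SO", max_origins = 1L, root_forced = FALSE),
    BOR1 = list(name = "BOR1", max_origins = 2L, root_forced = FALSE),
    BOR3 = list(name = "BOR3", max_origins = 4L, root_forced = FALSE),
    BOR7 = list(name = "BOR7", max_origins = 8L, root_forced = FALSE),
    BOR15 = list(name = "BOR15", max_origins = 16L, root_forced = FALSE)
  )
  if (!name %in% names(specs)) {
    abort(paste0("unknown model: ", name, " (expected LO, SO, BOR1, BOR3, BOR7 or BOR15)"))
  }
  specs[[name]]
}

#' Coerce a PAP row to a logical presence vector in tree leaf order
#' @noRd
row_presence <- function(tree, pap_row) {
  lv <- tree$labels[seq_len(tree$n_leaf)]
  if (!is.null(names(pap_row))) {
    idx <- match(lv, names(pap_row))
    if (anyNA(idx)) abort("PAP row is missing taxa present in the tree")
    pap_row <- pap_row[idx]
  } else if (length(pap_row) != tree$n_leaf) {
    abort("unnamed PAP row must have one entry per leaf, in tree leaf order")
  }
  pres <- as.integer(pap_row) == 1L
  if (!any(pres)) abort("character must be present in at least one taxon")
  pres
}

#' Loss nodes: maximal all-absent clades inside an origin's subtree
#'
#' A loss is placed at every node below `origin` whose descendant leaves are
#' all absent while its parent still has at least one present descendant.
#' This is the minimum loss set given the origin.
#' @noRd
losses_in_subtree <- function(tree, origin, cnt) {
  if (tree$is_leaf[origin]) return(integer(0))
  out <- integer(0)
  stack <- c(tree$kid1[origin], tree$kid2[origin])
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (cnt[v] == 0L) {
      out <- c(out, v) # whole clade absent: one loss, do not descend
    } else if (!tree$is_leaf[v]) {
      stack <- c(stack, tree$kid1[v], tree$kid2[v])
    }
  }
  sort(out)
}

#' Walk down from `v` to the MRCA of present leaves within its subtree
#' @noRd
descend_mrca <- function(tree, v, cnt) {
  while (!tree$is_leaf[v]) {
    a <- tree$kid1[v]
    b <- tree$kid2[v]
    if (cnt[a] > 0L && cnt[b] > 0L) break
    v <- if (cnt[a] > 0L) a else b
  }
  v
}

#' Infer a gain-loss scenario for one character
#'
#' Core parsimony routines of the method. All three work on the per-node
#' counts of present descendant leaves:
#' * `infer_lo()` places the single origin at the root and a loss at every
#'   maximal all-absent clade.
#' * `infer_so()` places the origin at the MRCA of the present leaves and
#'   infers losses as in LO inside that subtree.
#' * `infer_bork()` starts from the SO origin and repeatedly splits any
#'   origin whose subtree still contains an absent leaf into the two MRCAs
#'   of present leaves inside its child clades, while the total number of
#'   origins stays within the model's allowance. Splitting is breadth-first
#'   (FIFO) over origins in discovery order; each executed split records
#'   the resulting origin pair as siblings (these pairs become the lateral
#'   edges of the MLN). Losses are then inferred LO-style inside each final
#'   origin's subtree.
#'
#' @param tree A [reference_tree][as_reference_tree].
#' @param pap_row Binary presence vector, named by taxon or in tree leaf
#'   order, with at least one presence.
#' @param spec A [model_spec] with `max_origins >= 2` (for `infer_bork`).
#' @return A list with `origins` (ordered node indices; first = primary),
#'   `losses` (sorted node indices) and `sibling_pairs` (two-column matrix
#'   of origin pairs produced together by one split).
#' @export
infer_lo <- function(tree, pap_row) {
  pres <- row_presence(tree, pap_row)
  cnt <- presence_counts(tree, pres)
  list(
    origins = tree$root,
    losses = losses_in_subtree(tree, tree$root, cnt),
    sibling_pairs = matrix(integer(0), ncol = 2L)
  )
}

#' @rdname infer_lo
#' @export
infer_so <- function(tree, pap_row) {
  pres <- row_presence(tree, pap_row)
  cnt <- presence_counts(tree, pres)
  origin <- descend_mrca(tree, tree$root, cnt)
  list(
    origins = origin,
    losses = losses_in_subtree(tree, origin, cnt),
    sibling_pairs = matrix(integer(0), ncol = 2L)
  )
}

#' @rdname infer_lo
#' @export
infer_bork <- function(tree, pap_row, spec) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (spec$max_origins < 2L) {
    abort("infer_bork() needs a model with max_origins >= 2 (BOR1/3/7/15)")
  }
  pres <- row_presence(tree, pap_row)
  cnt <- presence_counts(tree, pres)
  queue <- descend_mrca(tree, tree$root, cnt)
  final <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  total <- 1L
  while (length(queue) > 0) {
    v <- queue[1L]
    queue <- queue[-1L]
    has_absent <- !tree$is_leaf[v] && cnt[v] < length(tree$leaf_desc[[v]])
    if (has_absent && total + 1L <= spec$max_origins) {
      # v is the MRCA of its present leaves, so both child clades hold some
      oa <- descend_mrca(tree, tree$kid1[v], cnt)
      ob <- descend_mrca(tree, tree$kid2[v], cnt)
      pairs <- rbind(pairs, c(oa, ob))
      queue <- c(queue, oa, ob)
      total <- total + 1L
    } else {
      final <- c(final, v)
    }
  }
  list(
    origins = final,
    losses = sort(unlist(lapply(final, losses_in_subtree, tree = tree, cnt = cnt))),
    sibling_pairs = pairs
  )
}

#' Replay a gain-loss scenario over the tree
#'
#' Propagates each origin's presence down the tree, switching presence off
#' at loss nodes (and everywhere below them, unless a later origin
#' re-establishes it; with valid scenarios origins are disjoint so this
#' never happens). Used both for ancestral inventories and for the
#' round-trip invariant that a scenario reproduces its PAP row.
#'
#' @param tree A [reference_tree][as_reference_tree].
#' @param origins,losses Node index vectors.
#' @return Logical presence vector over all nodes (leaves first).
#' @export
replay_scenario <- function(tree, origins, losses) {
  pres <- logical(tree$n_node)
  is_origin <- logical(tree$n_node)
  is_origin[origins] <- TRUE
  is_loss <- logical(tree$n_node)
  is_loss[losses] <- TRUE
  for (v in rev(tree$postorder)) { # preorder: parents before children
    pres[v] <- if (is_origin[v]) {
      TRUE
    } else if (v == tree$root || is_loss[v]) {
      FALSE
    } else {
      pres[tree$parent[v]]
    }
  }
  pres
}

#' Infer gain-loss scenarios for every character of a PAP matrix
#'
#' @param tree A [reference_tree][as_reference_tree].
#' @param pap A binary PAP matrix (characters x taxa); column names must
#'   match the tree's leaf labels.
#' @param model Model name (see [model_spec]) or a spec list.
#' @return A `gl_scenarios` tibble with one row per character: `character`,
#'   `n_origins`, `n_losses`, `n_borrowings`, plus list-columns `origins`,
#'   `losses` and `sibling_pairs` holding node indices. The tree and model
#'   are attached as attributes.
#' @examples
#' tr <- read_newick(textConnection("((A,B),(C,D));"))
#' pap <- matrix(c(1L, 0L, 1L, 0L), 1, dimnames = list("cog1", c("A", "B", "C", "D")))
#' infer_scenarios(tr, pap, "BOR1")
#' @export
infer_scenarios <- function(tree, pap, model = "SO") {
  tree <- as_reference_tree(tree)
  spec <- if (is.character(model)) model_spec(model) else model
  pap <- validate_pap(pap)
  lv <- tree$labels[seq_len(tree$n_leaf)]
  idx <- match(lv, colnames(pap))
  if (anyNA(idx)) {
    abort("PAP taxa do not cover the tree's leaf labels")
  }
  pap <- pap[, idx, drop = FALSE]
  infer_one <- switch(spec$name,
    LO = function(row) infer_lo(tree, row),
    SO = function(row) infer_so(tree, row),
    function(row) infer_bork(tree, row, spec)
  )
  scen <- lapply(seq_len(nrow(pap)), function(i) infer_one(pap[i, ]))
  out <- tibble(
    character = rownames(pap),
    n_origins = vapply(scen, function(s) length(s$origins), integer(1)),
    n_losses = vapply(scen, function(s) length(s$losses), integer(1)),
    origins = lapply(scen, `[[`, "origins"),
    losses = lapply(scen, `[[`, "losses"),
    sibling_pairs = lapply(scen, `[[`, "sibling_pairs")
  )
  out$n_borrowings <- out$n_origins - 1L
  attr(out, "tree") <- tree
  attr(out, "model") <- spec$name
  class(out) <- c("gl_scenarios", class(out))
  out
}

#' @export
print.gl_scenarios <- function(x, ...) {
  cat(sprintf(
    "<gl_scenarios: %d characters, model %s; mean losses %.2f, mean borrowings %.2f>\n",
    nrow(x), attr(x, "model"), mean(x$n_losses), mean(x$n_borrowings)
  ))
  NextMethod()
}

#' Ancestral and contemporary inventory sizes under a scenario set
#'
#' The inventory (vocabulary size, gene content) of a node is the number of
#' characters present at that node when each scenario's origins are
#' replayed down the tree and switched off at loss nodes. Leaf inventories
#' always equal the PAP column sums. The alternative `"origin_count"` mode
#' instead counts, per node, the characters whose scenario places an origin
#' exactly there.
#'
#' @param tree A [reference_tree][as_reference_tree].
#' @param scenarios A `gl_scenarios` object from [infer_scenarios].
#' @param mode `"presence"` (default) or `"origin_count"`.
#' @return An `inventory_profile`: a list with `size` (named integer vector
#'   over all nodes), `ancestral` (internal-node sizes, root included) and
#'   `contemporary` (leaf sizes).
#' @export
ancestral_inventory <- function(tree, scenarios, mode = c("presence", "origin_count")) {
  mode <- match.arg(mode)
  tree <- as_reference_tree(tree)
  st <- attr(scenarios, "tree")
  if (!is.null(st) && st$n_node != tree$n_node) {
    abort("scenarios were inferred on a different tree")
  }
  size <- integer(tree$n_node)
  if (mode == "presence") {
    for (i in seq_len(nrow(scenarios))) {
      size <- size + replay_scenario(tree, scenarios$origins[[i]], scenarios$losses[[i]])
    }
  } else {
    tab <- tabulate(unlist(scenarios$origins), nbins = tree$n_node)
    size <- as.integer(tab)
  }
  size <- as.integer(size)
  names(size) <- tree$labels
  structure(
    list(
      size = size,
      ancestral = size[!tree$is_leaf],
      contemporary = size[tree$is_leaf],
      mode = mode,
      tree = tree
    ),
    class = "inventory_profile"
  )
}

#' @export
print.inventory_profile <- function(x, ...) {
  cat(sprintf(
    "<inventory_profile (%s): %d ancestral nodes (median %s), %d contemporary (median %s)>\n",
    x$mode, length(x$ancestral), median(x$ancestral),
    length(x$contemporary), median(x$contemporary)
  ))
  invisible(x)
}

#' Event-count summaries of a scenario set
#'
#' @param scenarios A `gl_scenarios` object.
#' @return A list with `mean_losses`, `mean_borrowings` and
#'   `origin_histogram` (a tibble of `n_origins` and `n_characters`).
#' @export
event_counts <- function(scenarios) {
  if (nrow(scenarios) == 0) abort("empty scenario set")
  hist <- dplyr::count(tibble(n_origins = scenarios$n_origins),
                       .data$n_origins, name = "n_characters")
  list(
    mean_losses = mean(scenarios$n_losses),
    mean_borrowings = mean(scenarios$n_borrowings),
    origin_histogram = hist
  )
}

#' Select the borrowing allowance by the uniformitarian criterion
#'
#' For each candidate model, in order of increasing borrowing allowance,
#' scenarios are inferred for every character, the ancestral (internal
#' node) and contemporary (leaf) inventory sizes are computed, and the two
#' distributions are compared with a two-sided Wilcoxon rank-sum test. The
#' accepted model is the first whose ancestral sizes are *not*
#' significantly different from the contemporary ones (`p > alpha`): the
#' minimum borrowing allowance under which ancestral inventories look like
#' modern ones. The fraction of interquartile range
#' `(median(ancestral) - median(contemporary)) / IQR(contemporary)`
#' is reported as an effect-size summary for each model.
#'
#' @param tree A [reference_tree][as_reference_tree].
#' @param pap A binary PAP matrix.
#' @param alpha Significance level for the Wilcoxon test (default 0.05).
#' @param models Candidate model names, ordered by increasing allowance.
#' @param mode Inventory semantics passed to [ancestral_inventory].
#' @return An `mln_model_selection` object: list with `table` (one row per
#'   model: `model`, `max_origins`, `p_value`, `iqr_fraction`,
#'   `mean_losses`, `mean_borrowings`, `accepted`), `accepted_model`,
#'   `none_accepted`, `alpha`, and `scenarios`/`inventory` for the accepted
#'   model.
#' @export
select_model <- function(tree, pap,
                         alpha = 0.05,
                         models = c("LO", "SO", "BOR1", "BOR3", "BOR7", "BOR15"),
                         mode = c("presence", "origin_count")) {
  mode <- match.arg(mode)
  tree <- as_reference_tree(tree)
  if (tree$n_node - tree$n_leaf < 2L) {
    abort("model selection needs at least 2 internal nodes")
  }
  pap <- validate_pap(pap)
  rows <- list()
  accepted <- NULL
  acc_scen <- NULL
  acc_inv <- NULL
  for (m in models) {
    scen <- infer_scenarios(tree, pap, m)
    inv <- ancestral_inventory(tree, scen, mode = mode)
    p <- wilcoxon_rank_sum(inv$ancestral, inv$contemporary)
    iqr_f <- tryCatch(
      iqr_fraction(inv$ancestral, inv$contemporary),
      error = function(e) NA_real_
    )
    ev <- event_counts(scen)
    rows[[m]] <- tibble(
      model = m, max_origins = model_spec(m)$max_origins,
      p_value = p, iqr_fraction = iqr_f,
      mean_losses = ev$mean_losses, mean_borrowings = ev$mean_borrowings
    )
    if (is.null(accepted) && p > alpha) {
      accepted <- m
      acc_scen <- scen
      acc_inv <- inv
    }
  }
  tab <- dplyr::bind_rows(rows)
  none <- is.null(accepted)
  if (none) {
    accepted <- models[length(models)]
    acc_scen <- infer_scenarios(tree, pap, accepted)
    acc_inv <- ancestral_inventory(tree, acc_scen, mode = mode)
  }
  tab$accepted <- tab$model == accepted & !none
  structure(
    list(
      table = tab, accepted_model = accepted, none_accepted = none,
      alpha = alpha, scenarios = acc_scen, inventory = acc_inv, tree = tree
    ),
    class = "mln_model_selection"
  )
}

#' @export
print.mln_model_selection <- function(x, ...) {
  cat(sprintf(
    "<mln_model_selection: accepted %s%s (alpha = %g)>\n",
    x$accepted_model, if (x$none_accepted) " [none accepted: last model reported]" else "",
    x$alpha
  ))
  print(x$table)
  invisible(x)
}
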