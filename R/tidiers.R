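#' Tidy a scenario set into a flat report table
#'
#' @param x A `gl_scenarios` object from [infer_scenarios].
#' @param ... Unused.
#' @return A tibble with one row per character: `character`, `n_origins`,
#'   `origins` (node labels, comma-separated, primary first), `n_losses`,
#'   `losses` (node labels), `n_borrowings`.
#' @export
tidy.gl_scenarios <- function(x, ...) {
  tree <- attr(x, "tree")
  lab <- function(idx) paste(tree$labels[idx], collapse = ",")
  tibble(
    character = x$character,
    n_origins = x$n_origins,
    origins = vapply(x$origins, lab, character(1)),
    n_losses = x$n_losses,
    losses = vapply(x$losses, lab, character(1)),
    n_borrowings = x$n_borrowings
  )
}

#' @rdname tidy.gl_scenarios
#' @return `glance()`: a one-row tibble with `n_characters`, `model`,
#'   `mean_losses`, `mean_borrowings`, `total_borrowings`.
#' @export
glance.gl_scenarios <- function(x, ...) {
  ev <- event_counts(x)
  tibble(
    n_characters = nrow(x),
    model = attr(x, "model"),
    mean_losses = ev$mean_losses,
    mean_borrowings = ev$mean_borrowings,
    total_borrowings = sum(x$n_borrowings)
  )
}

#' Tidy methods for model selection results
#'
#' @param x An `mln_model_selection` object from [select_model].
#' @param ... Unused.
#' @return `tidy()`: the per-model table (model, max_origins, p_value,
#'   iqr_fraction, mean_losses, mean_borrowings, accepted). `glance()`:
#'   a one-row tibble for the accepted model.
#' @export
tidy.mln_model_selection <- function(x, ...) {
  x$table
}

#' @rdname tidy.mln_model_selection
#' @export
glance.mln_model_selection <- function(x, ...) {
  row <- x$table[x$table$model == x$accepted_model, ]
  dplyr::mutate(row, none_accepted = x$none_accepted, alpha = x$alpha)
}

#' Tidy methods for lateral networks
#'
#' @param x A `lateral_network` object from [build_mln].
#' @param ... Unused.
#' @return `tidy()`: the lateral edge table with node labels and kinds.
#'   `glance()`: one row of whole-network statistics (see [graph_stats]).
#' @export
tidy.lateral_network <- function(x, ...) {
  tree <- x$tree
  kind <- ifelse(tree$is_leaf, "external", "internal")
  tibble(
    from = tree$labels[x$edges$node_a],
    to = tree$labels[x$edges$node_b],
    from_kind = kind[x$edges$node_a],
    to_kind = kind[x$edges$node_b],
    weight = x$edges$weight
  )
}

#' @rdname tidy.lateral_network
#' @export
glance.lateral_network <- function(x, ...) {
  gs <- graph_stats(x)
  dplyr::mutate(gs,
    total_lateral_weight = sum(x$edges$weight),
    model = x$model %||% NA_character_
  )
}

#' Tidy an inventory profile
#'
#' @param x An `inventory_profile` from [ancestral_inventory].
#' @param ... Unused.
#' @return A tibble with `node`, `label`, `kind` and `inventory`.
#' @export
tidy.inventory_profile <- function(x, ...) {
  tree <- x$tree
  tibble(
    node = seq_len(tree$n_node),
    label = tree$labels,
    kind = ifelse(tree$is_leaf, "contemporary", "ancestral"),
    inventory = as.integer(x$size)
  )
}

#' Tidy a community partition
#'
#' @param x A `community_partition` from
#'   [leading_eigenvector_communities].
#' @param ... Unused.
#' @return `tidy()`: tibble of `taxon` and `module`. `glance()`: one row
#'   with `n_modules` and modularity `q`.
#' @export
tidy.community_partition <- function(x, ...) {
  tibble(taxon = names(x$membership), module = unname(x$membership))
}

#' @rdname tidy.community_partition
#' @export
glance.community_partition <- function(x, ...) {
  tibble(n_modules = x$n_modules, q = x$q)
}
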