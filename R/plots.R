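#' Plot ancestral vs contemporary inventory-size distributions
#'
#' Density view of the uniformitarian comparison: under a well-calibrated
#' borrowing allowance the ancestral (internal node) inventory sizes
#' should resemble the contemporary (leaf) ones.
#'
#' @param object An `inventory_profile` from [ancestral_inventory].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.inventory_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$inventory, colour = .data$kind)) +
    ggplot2::geom_density() +
    ggplot2::labs(
      x = "inventory size (characters present)",
      y = "density", colour = NULL,
      title = "Ancestral vs contemporary inventory sizes"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the model-selection profile
#'
#' Shows, per borrowing-allowance model, the fraction of interquartile
#' range by which ancestral inventories deviate from contemporary ones,
#' with accepted models highlighted.
#'
#' @param object An `mln_model_selection` from [select_model].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mln_model_selection <- function(object, ...) {
  df <- object$table
  df$model <- factor(df$model, levels = df$model)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$iqr_fraction,
                                   fill = .data$accepted)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = NULL, y = "(median ancestral - median contemporary) / IQR contemporary",
      fill = "accepted",
      title = "Borrowing-allowance model selection"
    ) +
    ggplot2::theme_minimal()
}

#' Plot lateral-network degree and edge-weight distributions
#'
#' @param object A `lateral_network` from [build_mln].
#' @param type `"connectivity"` (lateral neighbours per node) or
#'   `"weights"` (lateral edge-weight histogram).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lateral_network <- function(object, type = c("connectivity", "weights"), ...) {
  type <- match.arg(type)
  if (type == "connectivity") {
    df <- degree_stats(object)$connectivity
    ggplot2::ggplot(df, ggplot2::aes(x = .data$connectivity, fill = .data$kind)) +
      ggplot2::geom_bar() +
      ggplot2::labs(
        x = "lateral connectivity (distinct neighbours)", y = "nodes",
        title = "MLN lateral connectivity distribution"
      ) +
      ggplot2::theme_minimal()
  } else {
    df <- edge_weight_histogram(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$n_edges)) +
      ggplot2::geom_col() +
      ggplot2::labs(
        x = "laterally shared characters per edge", y = "edges",
        title = "MLN lateral edge-weight distribution"
      ) +
      ggplot2::theme_minimal()
  }
}
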