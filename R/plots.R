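#' Plot a response-feature screen
#'
#' Features ordered by baseline-vs-donor q-value, with the significance
#' cutoff drawn and selected (three-criterion) features highlighted.
#'
#' @param object An `fmt_screen` from [screen_response_features()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fmt_screen
#' @export
autoplot.fmt_screen <- function(object, ...) {
  alpha <- attr(object, "alpha")
  df <- as_tibble(object) |>
    dplyr::arrange(.data$q_baseline_vs_donor) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot(df, aes(x = .data$rank, y = -log10(.data$q_baseline_vs_donor),
    colour = .data$selected, shape = .data$direction)) +
    geom_point() +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    labs(
      x = "features ordered by q-value",
      y = expression(-log[10] ~ "q (baseline vs donor)"),
      colour = "selected", shape = NULL,
      title = sprintf("Response screen (%s): %d of %d features selected",
        attr(object, "feature_class"), sum(object$selected), nrow(object))
    ) +
    theme_minimal()
}

#' Plot a typed correlation network
#'
#' Force-directed layout with nodes coloured by class (clinical / taxon /
#' metabolite) and edges coloured by correlation sign, the conventional
#' rendering of ternary host-microbe-metabolite networks.
#'
#' @param object An `fmt_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fmt_network
#' @export
autoplot.fmt_network <- function(object, ...) {
  g <- as_igraph(object)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes |>
    dplyr::mutate(x = xy[match(.data$id, igraph::V(g)$name), 1],
      y = xy[match(.data$id, igraph::V(g)$name), 2])
  edges <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, "id", xa = "x", ya = "y"),
      by = c(a = "id")) |>
    dplyr::left_join(dplyr::select(nodes, "id", xb = "x", yb = "y"),
      by = c(b = "id"))
  p <- ggplot()
  if (nrow(edges)) {
    p <- p + geom_segment(
      data = edges,
      aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
        colour = .data$sign),
      alpha = 0.7
    ) +
      scale_colour_manual(values = c(positive = "#c0392b", negative = "#2980b9"))
  }
  p +
    geom_point(data = nodes, aes(x = .data$x, y = .data$y, fill = .data$node_class),
      shape = 21, size = 3) +
    labs(fill = "node class", colour = "correlation",
      title = sprintf("%s network: %d edges",
        ifelse(is.na(object$context), "correlation", object$context),
        nrow(object$edges))) +
    theme_void()
}

#' Plot ordination scores
#'
#' Score plot of the first two components, coloured by class label for
#' PLS-DA fits (or a supplied grouping).
#'
#' @param object An `fmt_ordination`.
#' @param groups Optional grouping vector (one value per sample) used for
#'   colour when the fit carries no labels.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fmt_ordination
#' @export
autoplot.fmt_ordination <- function(object, groups = NULL, ...) {
  df <- tidy(object, matrix = "scores")
  comp <- setdiff(names(df), c("sample_id", "label"))[1:2]
  if (is.null(df$label) && !is.null(groups)) df$label <- as.character(groups)
  ev <- object$explained_variance
  lab <- function(i) {
    if (object$method == "pca") {
      sprintf("%s (%.1f%%)", comp[i], 100 * ev[i])
    } else {
      comp[i]
    }
  }
  mapping <- if (!is.null(df$label)) {
    aes(x = .data[[comp[1]]], y = .data[[comp[2]]], colour = .data$label)
  } else {
    aes(x = .data[[comp[1]]], y = .data[[comp[2]]])
  }
  ggplot(df, mapping) +
    geom_point(size = 2) +
    labs(x = lab(1), y = lab(2), colour = NULL,
      title = toupper(object$method)) +
    theme_minimal()
}

#' Boxplots of alpha diversity by group
#'
#' @param div Output of [alpha_diversity()].
#' @param groups Grouping vector, one value per sample.
#' @return A ggplot faceted by index.
#' @export
plot_alpha_diversity <- function(div, groups) {
  long <- div |>
    dplyr::mutate(group = as.character(groups)) |>
    tidyr::pivot_longer(cols = -c("sample_id", "group"),
      names_to = "index", values_to = "value")
  ggplot(long, aes(x = .data$group, y = .data$value, fill = .data$group)) +
    geom_boxplot(outlier.size = 0.8) +
    facet_wrap(~index, scales = "free_y") +
    labs(x = NULL, y = NULL, fill = NULL) +
    theme_minimal()
}
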