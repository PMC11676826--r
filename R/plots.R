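#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.network_layout <- function(g, seed) {
  xy <- .with_seed(seed, igraph::layout_with_fr(g))
  tibble::tibble(phenocode = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
}

#' Plot a disease network
#'
#' Force-directed layout with nodes coloured by disease category, sized by
#' the number of associated SNP/LD-block units, and link width scaled by
#' the link weight.
#'
#' @param object a `phenet` or `sub_phenet` object.
#' @param seed layout seed.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.phenet <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  lay <- .network_layout(g, seed)
  wcol <- .weight_column(object)
  edges <- object$links |>
    dplyr::left_join(lay, by = c(code_a = "phenocode")) |>
    dplyr::left_join(lay, by = c(code_b = "phenocode"),
                     suffix = c("", "_end"))
  nodes <- dplyr::left_join(object$nodes, lay, by = "phenocode")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_end,
                   yend = .data$y_end, linewidth = .data[[wcol]]),
      colour = "grey70") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$category,
                   size = .data$n_units)) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::scale_size(range = c(1.5, 6), guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "category")
}

#' Plot a directed trajectory network
#'
#' @param object a `directed_phenet` object.
#' @param seed layout seed.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.directed_phenet <- function(object, seed = 1L, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  g <- as_igraph(object)
  lay <- .network_layout(g, seed)
  edges <- object$arcs |>
    dplyr::left_join(lay, by = c(first = "phenocode")) |>
    dplyr::left_join(lay, by = c(second = "phenocode"),
                     suffix = c("", "_end"))
  nodes <- dplyr::left_join(object$nodes, lay, by = "phenocode")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_end,
                   yend = .data$y_end),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey50") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$prevalence,
                   colour = .data$mortality,
                   shape = factor(.data$level))) +
    ggplot2::scale_size(range = c(2, 7), guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "mortality rate", shape = "level")
}

#' Plot a permutation null distribution
#'
#' Histogram of the null replicates with the observed statistic marked.
#'
#' @param object a `null_distribution` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.null_distribution <- function(object, ...) {
  df <- tibble::tibble(value = object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(x = object$statistic, y = "replicates",
                  title = paste("observed vs", object$n_reps,
                                "label-shuffle replicates")) +
    ggplot2::theme_minimal()
}

#' Heat map of category-interaction Z-scores
#'
#' @param z_table output of [category_z_scores()].
#' @param significant_only show values only for Bonferroni-significant
#'   pairs (default `TRUE`).
#' @return a ggplot object.
#' @export
plot_category_z <- function(z_table, significant_only = TRUE) {
  df <- z_table
  df$label <- ifelse(!significant_only | df$significant,
                     sprintf("%.1f", df$z), "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cat_i, y = .data$cat_j,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", na.value = "grey90") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z")
}
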