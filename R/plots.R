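#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and summary methods for result objects
#'
#' `tidy()` returns the result as a plain tibble (one row per tested
#' pair or label); `glance()` a one-row summary with the number of tests
#' and of significant calls.
#'
#' @param x An `interaction_contrast` or `diff_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidyimc-tidiers
NULL

#' @rdname tidyimc-tidiers
#' @export
tidy.interaction_contrast <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname tidyimc-tidiers
#' @export
glance.interaction_contrast <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_tested = sum(!is.na(x$p)),
    n_significant = sum(x$significant, na.rm = TRUE),
    alpha = attr(x, "alpha") %||% 0.05
  )
}

#' @rdname tidyimc-tidiers
#' @export
tidy.diff_result <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname tidyimc-tidiers
#' @export
glance.diff_result <- function(x, ...) {
  tibble::tibble(
    n_comparisons = nrow(x),
    n_tested = sum(!is.na(x$p_wilcoxon)),
    n_significant = sum(x$p_adj < (attr(x, "alpha") %||% 0.05), na.rm = TRUE),
    alpha = attr(x, "alpha") %||% 0.05
  )
}

unclass_result <- function(x) {
  class(x) <- setdiff(class(x), c("interaction_contrast", "diff_result",
                                  "interaction_scores"))
  x
}

#' Plot a region map
#'
#' @param rm A `region_map`.
#' @return A ggplot raster of the region labels.
#' @export
plot_region_map <- function(rm) {
  df <- tidyr::expand_grid(i = seq_len(nrow(rm$labels)),
                           j = seq_len(ncol(rm$labels)))
  df$label <- as.vector(t(rm$labels))  # row-major expand_grid order
  df$region <- ifelse(df$label == 0, "background",
                      unname(rm$legend[as.character(df$label)]))
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$j - 0.5) * rm$pixel_size,
    y = (.data$i - 0.5) * rm$pixel_size, fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "region") +
    ggplot2::theme_minimal()
}

#' Box plots of per-sample composition or positivity by group
#'
#' Median and interquartile-range boxes of per-sample values, one facet
#' per stratum, matching the layout of differential-abundance figures.
#'
#' @param values Output of [per_sample_proportions()] or
#'   [positive_fraction()].
#' @return A ggplot.
#' @export
plot_composition <- function(values) {
  key <- if ("label" %in% names(values)) "label" else "marker"
  value <- if ("proportion" %in% names(values)) "proportion" else "fraction"
  ggplot2::ggplot(values, ggplot2::aes(
    x = .data[[key]], y = .data[[value]], fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, position = "dodge") +
    ggplot2::facet_wrap(~stratum, scales = "free_y") +
    ggplot2::labs(x = NULL, y = value, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Interaction-contrast grid plot
#'
#' One cell per type pair: paired points show the mean interaction score
#' u = L(r) - r per group (left Control, right ONJ), point size scales
#' with the absolute group difference, and pairs significant after BH
#' adjustment get a bold black outline.
#'
#' @param object An `interaction_contrast`.
#' @param radius Which radius to plot (default: smallest present).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.interaction_contrast <- function(object, radius = NULL, ...) {
  df <- tibble::as_tibble(unclass_result(object))
  radius <- radius %||% min(df$radius)
  df <- df[df$radius == radius, ]
  long <- tidyr::pivot_longer(df, c("mean_u_control", "mean_u_onj"),
                              names_to = "grp", values_to = "u")
  long$grp <- ifelse(long$grp == "mean_u_control", "Control", "ONJ")
  long$xoff <- ifelse(long$grp == "Control", -0.17, 0.17)
  ggplot2::ggplot(long, ggplot2::aes(
    x = as.numeric(factor(.data$type_b)) + .data$xoff,
    y = .data$type_a)) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$u,
                                     size = abs(.data$diff),
                                     stroke = ifelse(.data$significant, 1.6, 0.2)),
                        shape = 21, colour = "black") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::scale_x_continuous(
      breaks = seq_along(levels(factor(long$type_b))),
      labels = levels(factor(long$type_b))) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean u",
                  size = "|ONJ - Control|",
                  title = paste0("Spatial interaction contrast, r = ",
                                 radius, " µm")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scatter plot of an embedding coloured by a label
#'
#' @param embedding Tibble from [embed_cells()].
#' @param cells The classified `cell_table` (for label lookup).
#' @param colour_by Column of `cells` to colour by (default `"level1"`).
#' @return A ggplot.
#' @export
plot_embedding <- function(embedding, cells, colour_by = "level1") {
  df <- dplyr::left_join(
    embedding,
    tibble::as_tibble(cells)[, c("cell_id", colour_by)],
    by = "cell_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$umap1, .data$umap2,
                                   colour = .data[[colour_by]])) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::labs(colour = colour_by) +
    ggplot2::theme_minimal()
}
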