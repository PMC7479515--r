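#' @importFrom ggplot2 autoplot
NULL

#' Kaplan-Meier curves
#'
#' Step survival curves per group with censoring ticks.
#'
#' @param object a `km_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot km_result
#' @export
autoplot.km_result <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, n_risk = max(.x$n_risk),
                     n_event = 0L, estimate = 1), .x)) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$estimate,
                                  color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(d, .data$n_event == 0,
                                             .data$time > 0),
                        shape = 3, size = 1.5) +
    ggplot2::labs(
      x = "time (months)", y = "survival probability", color = NULL,
      subtitle = sprintf("log-rank chi-square = %.2f, p = %.3g",
                         object$chisq, object$p_value)
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Copy-number profile heatmap
#'
#' Cells by genomic windows, window means shown on a diverging scale with
#' chromosome boundaries marked. Cells are ordered by hierarchical
#' clustering of their profiles.
#'
#' @param object a `cna_profile`.
#' @param cap color-scale saturation (default 1).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cna_profile
#' @export
autoplot.cna_profile <- function(object, cap = 1, ...) {
  w <- object$windows
  ord <- stats::hclust(stats::dist(t(w)), method = "ward.D2")$order
  d <- tibble::as_tibble(w, rownames = "window_id") |>
    tidyr::pivot_longer(-"window_id", names_to = "cell_id",
                        values_to = "value") |>
    dplyr::left_join(object$window_info |>
                       dplyr::mutate(window_id = rownames(w)),
                     by = "window_id") |>
    dplyr::mutate(
      cell_id = factor(.data$cell_id, levels = colnames(w)[ord]),
      window = match(.data$window_id, rownames(w)),
      value = pmin(pmax(.data$value, -cap), cap)
    )
  bounds <- d |>
    dplyr::distinct(.data$window, .data$chrom) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(x = max(.data$window), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$window, .data$cell_id,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = bounds$x + 0.5, linewidth = 0.2) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-cap, cap)) +
    ggplot2::labs(x = "genomic window", y = NULL,
                  fill = "relative\nexpression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Program-correlation heatmap
#'
#' @param object a `program_correlation`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot program_correlation
#' @export
autoplot.program_correlation <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(
      program_a = factor(.data$program_a, levels = object$order),
      program_b = factor(.data$program_b, levels = object$order)
    ) |>
    ggplot2::ggplot(ggplot2::aes(.data$program_a, .data$program_b,
                                 fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Scatter of per-cell state scores
#'
#' Two program scores against each other, colored by assigned state —
#' the standard two-axis view of a cellular hierarchy.
#'
#' @param scores wide score tibble (`cell_id` + program columns).
#' @param x,y program column names to plot.
#' @param states optional [assign_states()] tibble for coloring.
#' @return a ggplot.
#' @export
plot_state_scores <- function(scores, x, y, states = NULL) {
  d <- scores
  if (!is.null(states)) {
    d <- dplyr::left_join(d, states[c("cell_id", "state")], by = "cell_id")
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(.data[[x]], .data[[y]]))
  if (!is.null(states)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$state),
                                 size = 0.8)
  } else {
    p <- p + ggplot2::geom_point(size = 0.8)
  }
  p + ggplot2::theme_minimal()
}
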