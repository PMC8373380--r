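#' Plot the model's two response curves
#'
#' Dose-response view of a [gal_model()]: induced fraction and induced mean
#' log10 level against glucose on a log axis, with the E10 and F90
#' thresholds marked.
#'
#' @param object A `gal_model`.
#' @param glucose Glucose grid to draw over (default 200 log-spaced points
#'   covering the standard titration with margin).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gal_model <- function(object, glucose = 10^seq(-3, 0.5, length.out = 200),
                               ...) {
  curves <- induction_curves(glucose, object)
  long <- tidyr::pivot_longer(
    curves[, c("glucose", "induced_fraction", "induced_mean_log_level")],
    -"glucose",
    names_to = "curve", values_to = "value"
  )
  thr <- tibble(
    curve = c("induced_fraction", "induced_mean_log_level"),
    x = c(object$F90, object$E10)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$glucose, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      data = thr, ggplot2::aes(xintercept = .data$x), linetype = 2
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(
      ~curve,
      scales = "free_y", ncol = 1,
      labeller = ggplot2::as_labeller(c(
        induced_fraction = "induced fraction",
        induced_mean_log_level = "induced level (log10 relative)"
      ))
    ) +
    ggplot2::labs(x = "glucose (% w/v)", y = NULL)
}

#' Plot an induction profile as stacked condition histograms
#'
#' The standard flow-cytometry view of a titration: one expression
#' histogram per glucose concentration.
#'
#' @param object An `induction_profile`.
#' @param bins Histogram bins per condition.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.induction_profile <- function(object, bins = 64, ...) {
  cells <- object$cells
  cells$glucose_label <- factor(
    sprintf("%.4g%% glu", cells$glucose),
    levels = sprintf("%.4g%% glu", sort(unique(cells$glucose)))
  )
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$log_expression)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(~glucose_label, ncol = 1, strip.position = "right") +
    ggplot2::labs(
      x = "log10 relative expression", y = "cells",
      title = object$replicate_id
    )
}

#' Plot a phase diagram with its regime boundaries
#'
#' Scatter of the scanned grid points in log10(F90)-log10(E10) space,
#' colored by modality call, with the slope-1 bounding lines and the
#' ambiguous band between them.
#'
#' @param object A `phase_diagram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_diagram <- function(object, ...) {
  pts <- object$points
  if (object$basis == "measured") {
    pts$x <- log10(pts$F90_out)
    pts$y <- log10(pts$E10_out)
  } else {
    pts$x <- log10(pts$F90_in)
    pts$y <- log10(pts$E10_in)
  }
  pts <- pts[is.finite(pts$x) & is.finite(pts$y), ]
  p <- ggplot2::ggplot(
    pts,
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data$modality)
  ) +
    ggplot2::geom_abline(
      slope = 1, intercept = object$unimodal_intercept, linetype = 2
    ) +
    ggplot2::geom_abline(
      slope = 1, intercept = object$bimodal_intercept, linetype = 2
    ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "log10 F90 (% glucose)", y = "log10 E10 (% glucose)",
      colour = "modality"
    )
  p
}
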