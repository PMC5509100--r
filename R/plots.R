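#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a precision-recall curve
#'
#' @param object A `deltabind_pr` from [precision_recall()].
#' @param ... Unused.
#' @return A ggplot: the step-wise PR curve, with the positive-class
#'   prevalence (the random-ranking baseline) as a dashed reference line.
#' @exportS3Method ggplot2::autoplot
autoplot.deltabind_pr <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh", color = "#2166ac") +
    ggplot2::geom_hline(
      yintercept = object$prevalence,
      linetype = "dashed", color = "grey50"
    ) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      title = sprintf("AUPR (average precision) = %.3g", object$aupr),
      subtitle = sprintf(
        "%d positives / %d negatives; dashed line = prevalence (random baseline)",
        object$n_pos, object$n_neg
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot the fitted rank-difference mixture across windows
#'
#' @param object A `deltabind_diffmix` from [fit_diff_mixture()].
#' @param ... Unused.
#' @return A ggplot of the per-window category weights and shift against
#'   bound-condition mean rank, showing how the mixture varies with
#'   binding strength.
#' @exportS3Method ggplot2::autoplot
autoplot.deltabind_diffmix <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$windows,
    dplyr::all_of(c("pi_same", "pi_lowerG", "pi_higherG", "delta")),
    names_to = "parameter", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$center, y = .data$value)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(
      x = "Bound-condition mean rank (window center)",
      y = "Estimate",
      title = "Rank-difference mixture across rank windows"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the binding-probability calibration curve
#'
#' @param repro A `deltabind_repro` from [fit_reproducibility()].
#' @return A ggplot of P(bound | mean rank) against mean bound-condition
#'   rank (the isotonic calibration of the reproducibility posterior).
#' @export
plot_pa_curve <- function(repro) {
  stopifnot(inherits(repro, "deltabind_repro"))
  if (is.null(repro$pa_curve)) {
    stop("no pa_curve; fit with fit_reproducibility()", call. = FALSE)
  }
  dat <- tibble::tibble(rank = repro$pa_curve$x, pA = repro$pa_curve$y)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$pA)) +
    ggplot2::geom_line(color = "#b2182b") +
    ggplot2::labs(
      x = "Mean bound-condition rank", y = "P(bound | rank)",
      title = "Isotonic binding-probability calibration"
    ) +
    ggplot2::theme_minimal()
}
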