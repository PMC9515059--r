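#' Plot a viewport map
#'
#' Skin points coloured by feasibility / rejection reason, projected on
#' two patient axes.
#'
#' @param object a `viewport_map`.
#' @param axes which coordinates to draw (default x against z, the
#'   anterior view).
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.viewport_map <- function(object, axes = c("x", "z"), ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]],
                                       colour = .data$reason)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Ultrasound viewports",
                  colour = "rejection",
                  x = paste0(axes[1], " (mm)"), y = paste0(axes[2], " (mm)")) +
    ggplot2::theme_minimal()
}

#' Plot an annealing trace
#'
#' Objective and incumbent best per iteration, one panel per restart.
#' @param object an `anneal_result`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.anneal_result <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$iteration)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$objective), colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$best), colour = "firebrick") +
    ggplot2::facet_wrap(~restart, labeller = ggplot2::label_both) +
    ggplot2::labs(y = "blocking objective", x = "iteration",
                  title = "Simulated-annealing setup search") +
    ggplot2::theme_minimal()
}

#' Plot the dose distribution of a plan
#'
#' Per-region dose histograms with the prescription and maximum-dose
#' bounds marked.
#' @param object a `treatment_plan`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.treatment_plan <- function(object, ...) {
  df <- tibble(region = object$region, dose = object$dose)
  p <- object$constraints$prescribed_dose
  ggplot2::ggplot(df, ggplot2::aes(.data$dose)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = p, linetype = 2) +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "dose (Gy)", y = "voxels",
                  title = sprintf("stage-%s plan: coverage %.1f%%, %.0f MU",
                                  object$stage, 100 * object$coverage,
                                  object$total_mu)) +
    ggplot2::theme_minimal()
}

#' Plot scorer training loss
#' @param object a `beam_scorer`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.beam_scorer <- function(object, ...) {
  df <- tibble(epoch = seq_along(object$loss_history),
               loss = object$loss_history)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(y = "mean coverage-weighted loss",
                  title = "Beam-scorer training") +
    ggplot2::theme_minimal()
}
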