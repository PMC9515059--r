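#' Tidy a treatment plan
#'
#' One row per candidate beam with its optimized weight.
#' @param x a `treatment_plan`.
#' @param ... unused.
#' @return Tibble `beam`, `weight_mu`, `active`.
#' @exportS3Method generics::tidy
#' @export
tidy.treatment_plan <- function(x, ...) {
  tibble(beam = seq_along(x$weights), weight_mu = x$weights,
         active = x$weights > 1e-9)
}

#' @rdname tidy.treatment_plan
#' @exportS3Method generics::glance
#' @export
glance.treatment_plan <- function(x, ...) {
  tibble(stage = x$stage, coverage = x$coverage, total_mu = x$total_mu,
         objective_underdose = x$objective_underdose,
         n_beams = length(x$weights), n_active = sum(x$weights > 1e-9),
         prescribed_dose = x$constraints$prescribed_dose)
}

#' Tidy per-region dose summaries
#'
#' @param x a `treatment_plan`.
#' @param ... unused.
#' @return Tibble with per-region dose statistics.
#' @export
dose_summary <- function(x, ...) {
  tibble(region = x$region, dose = x$dose) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n_voxels = dplyr::n(), mean_dose = mean(.data$dose),
                     max_dose = max(.data$dose), min_dose = min(.data$dose))
}

#' @rdname tidy.treatment_plan
#' @exportS3Method generics::tidy
#' @export
tidy.anneal_result <- function(x, ...) x$trace

#' @rdname tidy.treatment_plan
#' @exportS3Method generics::glance
#' @export
glance.anneal_result <- function(x, ...) {
  tibble(best_objective = x$best_objective,
         restarts = x$schedule$restarts,
         iterations = x$schedule$iterations,
         acceptance_rate = mean(x$trace$accepted))
}

#' @rdname tidy.treatment_plan
#' @exportS3Method generics::glance
#' @export
glance.beam_scorer <- function(x, ...) {
  tibble(input = sprintf("%dx%dx%d", x$H, x$H, x$C),
         epochs = length(x$loss_history),
         final_loss = utils::tail(x$loss_history, 1),
         seed = x$seed)
}
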