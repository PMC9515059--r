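#' Named workflow variants
#'
#' Shorthand variant names accepted by [evaluate_cohort()]:
#' `no-robot`, `cnn` (scorer candidates, no robot), `rcb-br`, `rcb-brw`,
#' `rcb-bcw` (random candidates + setup search), `cnn-bc`, `cnn-bcw`
#' (scorer candidates + setup search).
#' @return Character vector of known variant names.
#' @export
workflow_variants <- function() {
  c("no-robot", "cnn", "rcb-br", "rcb-brw", "rcb-bcw", "cnn-bc", "cnn-bcw")
}

variant_args <- function(variant) {
  switch(variant,
    "no-robot" = list(candidates = "random", setup_objective = "none"),
    "cnn" = list(candidates = "cnn", setup_objective = "none"),
    "rcb-br" = list(candidates = "random", setup_objective = "BR"),
    "rcb-brw" = list(candidates = "random", setup_objective = "BRW"),
    "rcb-bcw" = list(candidates = "random", setup_objective = "BCW"),
    "cnn-bc" = list(candidates = "cnn", setup_objective = "BC"),
    "cnn-bcw" = list(candidates = "cnn", setup_objective = "BCW"),
    abort(paste0("unknown workflow variant: ", variant)))
}

#' Cohort-style evaluation
#'
#' Runs every workflow variant `repeats` times per phantom with distinct
#' derived candidate-beam seeds (repeated candidate draws reduce the
#' influence of sampling randomness) and tabulates plan quality and
#' setup-search outcomes. Stage failures are recorded per row and the run
#' continues. Deterministic per master seed; the derived seed of each row
#' is included so any row can be reproduced alone.
#'
#' @param bundles list of [prepare_phantom()] bundles.
#' @param variants variant names from [workflow_variants()].
#' @param repeats candidate-beam draws per (phantom, variant).
#' @param seed master seed.
#' @param scorer a `beam_scorer` for the scorer-based variants.
#' @param n_beams candidate beams per draw.
#' @param lift_offsets LIFT offsets for the robot variants.
#' @param schedule [anneal_schedule()] template.
#' @param two_stage also run MU minimization.
#' @param ... further arguments to [run_workflow()].
#' @return An `evaluation_report` tibble: one row per
#'   (phantom, variant, repeat) with coverage, total MU after both stages,
#'   objective value, blocked count and error message (NA when ok).
#' @export
evaluate_cohort <- function(bundles, variants = c("no-robot", "rcb-brw"),
                            repeats = 10, seed = 1L, scorer = NULL,
                            n_beams = 500, lift_offsets = 0,
                            schedule = anneal_schedule(),
                            two_stage = TRUE, ...) {
  stopifnot(length(bundles) >= 1, length(variants) >= 1)
  rows <- list()
  vps_cache <- vector("list", length(bundles))
  counter <- 0L
  for (i in seq_along(bundles)) {
    bd <- bundles[[i]]
    needs_vp <- any(vapply(variants,
                           function(v) variant_args(v)$setup_objective != "none",
                           TRUE))
    if (needs_vp && is.null(vps_cache[[i]])) {
      vps_cache[[i]] <- viewport_map(bd$ct, bd$grid)
    }
    for (v in variants) {
      va <- variant_args(v)
      for (rep_j in seq_len(repeats)) {
        counter <- counter + 1L
        # the repeat index (not the variant) drives the candidate seed, so
        # variants share candidate draws where their generator coincides
        run_seed <- derive_seed(seed, i * 131071L + rep_j)
        res <- tryCatch({
          wf <- run_workflow(bd, candidates = va$candidates,
                             setup_objective = va$setup_objective,
                             n_beams = n_beams, seed = run_seed,
                             scorer = scorer, schedule = schedule,
                             lift_offsets = lift_offsets,
                             two_stage = two_stage,
                             viewports = vps_cache[[i]], ...)
          tibble(
            phantom = i, variant = v, rep = rep_j, seed = run_seed,
            ptv_volume = bd$ptv_volume,
            coverage = wf$plan1$coverage,
            total_mu_coverage = wf$plan1$total_mu,
            total_mu = if (!is.null(wf$plan2)) wf$plan2$total_mu else
              wf$plan1$total_mu,
            objective = if (!is.null(wf$setup)) wf$setup$best_objective else
              NA_real_,
            n_blocked = length(wf$blocked),
            error = NA_character_)
        }, error = function(e) {
          tibble(phantom = i, variant = v, rep = rep_j, seed = run_seed,
                 ptv_volume = bd$ptv_volume, coverage = NA_real_,
                 total_mu_coverage = NA_real_, total_mu = NA_real_,
                 objective = NA_real_, n_blocked = NA_integer_,
                 error = conditionMessage(e))
        })
        rows[[counter]] <- res
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  attr(out, "config_hash") <- config_hash(list(
    variants = variants, repeats = repeats, n_beams = n_beams,
    lift_offsets = lift_offsets, seed = seed))
  class(out) <- unique(c("evaluation_report", class(out)))
  out
}

# small FNV-1a hash over the serialized configuration
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write an evaluation report
#'
#' CSV plus a JSON summary (per-variant means/SDs); byte-identical for
#' identical master seed and configuration (the config hash is embedded).
#' @param report an `evaluation_report`.
#' @param path base path (`.csv` appended).
#' @export
write_report <- function(report, path) {
  csv <- paste0(path, ".csv")
  con <- file(csv, "w")
  writeLines(paste0("# config_hash=", attr(report, "config_hash"),
                    " seed=", attr(report, "seed")), con)
  write.csv(as.data.frame(report), con, row.names = FALSE)
  close(con)
  summ <- report |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(mean_coverage = mean(.data$coverage),
                     sd_coverage = sd(.data$coverage),
                     mean_total_mu = mean(.data$total_mu),
                     mean_objective = mean(.data$objective),
                     n = dplyr::n())
  jsonlite::write_json(summ, paste0(path, ".json"), digits = NA,
                       na = "null")
  invisible(csv)
}

#' Wilcoxon rank-sum utility
#'
#' Standard two-sided rank-sum test (evaluation utility, not a method
#' contribution). Degenerate all-tied samples return p = 1 with a warning.
#'
#' @param x,y numeric samples.
#' @return The two-sided p value.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be nonempty")
  if (length(unique(c(x, y))) == 1) {
    warn("all observations tied; rank-sum test is degenerate")
    return(1)
  }
  suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
}

#' MU improvement vs PTV size
#'
#' Spearman correlation between PTV volume and the mean total-MU
#' improvement of scorer-generated over random candidates (positive
#' improvement = fewer MU with the scorer). Undefined (flagged) when no
#' phantom shows an improvement.
#'
#' @param report an `evaluation_report` containing both variants.
#' @param baseline,comparison variant names.
#' @return list: `estimate` (Spearman's rho, NA when undefined),
#'   `undefined` flag, and the per-phantom `table`.
#' @export
mu_improvement_vs_ptv_size <- function(report, baseline = "no-robot",
                                       comparison = "cnn") {
  tb <- report |>
    dplyr::filter(is.na(.data$error),
                  .data$variant %in% c(baseline, comparison)) |>
    dplyr::group_by(.data$phantom, .data$ptv_volume, .data$variant) |>
    dplyr::summarise(mu = mean(.data$total_mu), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "variant", values_from = "mu")
  if (nrow(tb) < 3) abort("need at least 3 phantoms")
  improvement <- tb[[baseline]] - tb[[comparison]]
  tb$improvement <- improvement
  if (all(abs(improvement) < 1e-9) || sd(improvement) == 0 ||
      sd(tb$ptv_volume) == 0) {
    return(list(estimate = NA_real_, undefined = TRUE, table = tb))
  }
  list(estimate = cor(tb$ptv_volume, improvement, method = "spearman"),
       undefined = FALSE, table = tb)
}
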