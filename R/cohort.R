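#' Prepare a phantom for planning
#'
#' Bundles everything the planners and the scorer need for one case:
#' generates the phantom, adds shells, builds the planning grid, the
#' feature label volume, the PTV centroid and volume, and the plan
#' constraints with shell maxima fixed at `shell_scale` times the base
#' shell bounds (or calibrated to 95% coverage when
#' `calibrate = TRUE`, which costs one bisection run of stage-1 solves).
#'
#' @param spec a [phantom_spec()] (e.g. from [random_phantom_spec()]).
#' @param resolution planning-grid resolution, mm.
#' @param shell_scale fixed shell-bound scale factor (see
#'   [calibrate_shell_dose()] for the base bounds).
#' @param constraints base [plan_constraints()].
#' @param calibrate calibrate shell bounds per phantom instead of using
#'   `shell_scale` (requires `calib_beams`).
#' @param calib_beams,calib_seed candidate-beam count and seed used only
#'   for calibration.
#' @return A `phantom_bundle` list: `phantom`, `ct`, `structures`, `grid`,
#'   `labels`, `centroid`, `ptv_volume` (cm^3), `constraints`.
#' @export
prepare_phantom <- function(spec, resolution = 3, shell_scale = 0.75,
                            constraints = plan_constraints(),
                            calibrate = FALSE, calib_beams = 500,
                            calib_seed = 1L) {
  ph <- generate_phantom(spec)
  st <- build_shells(ph$structures)
  grid <- voxelize(st, resolution)
  ct <- ph$ct
  cs <- constraints
  if (calibrate) {
    beams <- sample_candidate_beams(grid, calib_beams, seed = calib_seed)
    cal <- calibrate_shell_dose(ct, grid, beams, constraints = constraints)
    cs$shell3_max <- cal$shell3_max
    cs$shell9_max <- cal$shell9_max
  } else {
    cs$shell3_max <- shell_scale * constraints$prescribed_dose
    cs$shell9_max <- shell_scale * 0.6 * constraints$prescribed_dose
  }
  ptv <- st$masks$PTV
  structure(list(
    phantom = ph, ct = ct, structures = st, grid = grid,
    labels = structure_labels(st),
    centroid = mask_centroid(ptv, st$spacing, st$origin),
    ptv_volume = sum(ptv) * prod(st$spacing) / 1000,
    constraints = cs), class = "phantom_bundle")
}

#' Build a beam training set from a phantom cohort
#'
#' For every phantom and candidate-beam draw, solves the stage-1 coverage
#' plan and records each candidate beam's ground-truth weight `w_g` (its
#' MU in the plan; 0 for unused beams) and the plan's coverage `c_p`.
#' Examples are rebalanced with [subsample_training()] before the (costly)
#' feature images are computed, and uniformly thinned to at most
#' `max_examples`.
#'
#' @param bundles list of [prepare_phantom()] bundles.
#' @param n_plans candidate-beam draws (plans) per phantom.
#' @param n_beams candidate beams per plan.
#' @param seed master seed; plan `j` of phantom `i` uses a derived seed so
#'   any single plan is reproducible alone.
#' @param fspec [feature_spec()] for the feature images.
#' @param max_examples cap on the total number of training examples.
#' @param subsample_mode passed to [subsample_training()].
#' @return A `beam_training_set`: feature matrix `X` (one column per
#'   example), `w_g`, `c_p`, `phantom`, `ptv_volume`, `fspec`, `w_b`
#'   (measured imbalance ratio) and a `plans` summary tibble.
#' @export
build_training_data <- function(bundles, n_plans = 10, n_beams = 500,
                                seed = 1L, fspec = feature_spec_small(),
                                max_examples = 12000,
                                subsample_mode = "keep") {
  Xs <- list()
  meta <- list()
  plan_rows <- list()
  n_unw <- 0
  n_wt <- 0
  for (i in seq_along(bundles)) {
    bd <- bundles[[i]]
    for (j in seq_len(n_plans)) {
      sd <- derive_seed(seed, i * 1009L + j)
      beams <- sample_candidate_beams(bd$grid, n_beams, seed = sd)
      D <- compute_dose_matrix(bd$ct, bd$grid, beams)
      plan <- optimize_coverage(D, bd$constraints)
      ex <- beams
      ex$w_g <- plan$weights
      ex$c_p <- plan$coverage
      n_unw <- n_unw + sum(ex$w_g <= 0)
      n_wt <- n_wt + sum(ex$w_g > 0)
      keep <- subsample_training(ex, seed = derive_seed(sd, 7L),
                                 mode = subsample_mode)
      Xs[[length(Xs) + 1]] <-
        beam_features(bd$ct, bd$structures, keep, fspec, labels = bd$labels,
                      centroid = bd$centroid)
      cov_j <- plan$coverage
      mu_j <- plan$total_mu
      nw_j <- sum(plan$weights > 1e-9)
      meta[[length(meta) + 1]] <-
        tibble(phantom = i, plan = j, w_g = keep$w_g, c_p = keep$c_p,
               ptv_volume = bd$ptv_volume)
      plan_rows[[length(plan_rows) + 1]] <-
        tibble(phantom = i, plan = j, coverage = cov_j, total_mu = mu_j,
               n_weighted = nw_j)
    }
  }
  X <- do.call(cbind, Xs)
  md <- dplyr::bind_rows(meta)
  if (ncol(X) > max_examples) {
    keep <- with_seed(derive_seed(seed, 999983L),
                      sort(sample.int(ncol(X), max_examples)))
    X <- X[, keep, drop = FALSE]
    md <- md[keep, , drop = FALSE]
  }
  structure(list(X = X, w_g = md$w_g, c_p = md$c_p, phantom = md$phantom,
                 ptv_volume = md$ptv_volume, fspec = fspec,
                 w_b = max(1, n_unw / max(n_wt, 1)),
                 plans = dplyr::bind_rows(plan_rows)),
            class = "beam_training_set")
}

#' @export
print.beam_training_set <- function(x, ...) {
  cat(sprintf("<beam_training_set> %d examples (%d phantoms), %.0f%% weighted, w_b = %.1f\n",
              ncol(x$X), length(unique(x$phantom)),
              100 * mean(x$w_g > 0), x$w_b))
  invisible(x)
}

#' Stratified cross-validation folds by PTV volume
#'
#' Orders phantoms by PTV volume and deals them to folds snake-wise so the
#' volume distributions are similar in every fold.
#'
#' @param volumes per-phantom PTV volumes, cm^3.
#' @param folds number of folds.
#' @return Integer fold assignment per phantom.
#' @export
stratify_folds <- function(volumes, folds = 3) {
  ord <- order(volumes)
  fold <- integer(length(volumes))
  pattern <- c(seq_len(folds), rev(seq_len(folds)))
  fold[ord] <- rep_len(pattern, length(volumes))
  fold
}

#' Cross-validated scorer training
#'
#' Splits the phantoms into `folds` groups with similar PTV-size
#' distributions ([stratify_folds()]), trains one scorer per fold on the
#' remaining groups and predicts the held-out examples.
#'
#' @param data a `beam_training_set`.
#' @param folds number of folds (3).
#' @param ... passed to [train_beam_scorer()].
#' @return list with `scorers`, `fold` (per-phantom assignment tibble) and
#'   `holdout` (tibble `phantom`, `fold`, `w_g`, `w_p`).
#' @export
train_beam_scorer_cv <- function(data, folds = 3, ...) {
  ph <- sort(unique(data$phantom))
  if (length(ph) < 2 * folds) abort("need at least 2 phantoms per fold")
  vols <- vapply(ph, function(p) data$ptv_volume[match(p, data$phantom)], 0)
  fold_of <- stratify_folds(vols, folds)
  names(fold_of) <- ph
  scorers <- vector("list", folds)
  hold <- list()
  for (k in seq_len(folds)) {
    in_train <- data$phantom %in% ph[fold_of != k]
    sub <- data
    sub$X <- data$X[, in_train, drop = FALSE]
    sub$w_g <- data$w_g[in_train]
    sub$c_p <- data$c_p[in_train]
    scorers[[k]] <- train_beam_scorer(sub, ...)
    te <- which(!in_train)
    wp <- predict_weight(scorers[[k]], data$X[, te, drop = FALSE])
    hold[[k]] <- tibble(phantom = data$phantom[te], fold = k,
                        w_g = data$w_g[te], w_p = wp)
  }
  list(scorers = scorers,
       fold = tibble(phantom = ph, ptv_volume = vols, fold = fold_of),
       holdout = dplyr::bind_rows(hold))
}
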