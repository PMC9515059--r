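#' Run a treatment-planning workflow
#'
#' Composes the pipeline stages for one case: candidate-beam generation
#' (random heuristic or scorer-guided sampling), optional robot-setup
#' optimization under a blocking objective followed by removal of the
#' blocked beams, and the two-stage planning LP on the surviving beams.
#'
#' Workflow variants:
#' * `setup_objective = "none"` — no ultrasound robot (baseline);
#' * `"BR"`/`"BRW"` — setup search over the candidate set with unit /
#'   plan-MU weights (the plan weights come from a no-robot stage-1 plan
#'   on the same candidates);
#' * `"BC"`/`"BCW"` — setup search over scorer-generated candidates with
#'   unit / predicted weights;
#' * `bstar = TRUE` — the pose search is scored on the weighted subset of
#'   the candidates only, but the found pose is applied to the full
#'   original candidate set.
#'
#' @param bundle a [prepare_phantom()] bundle.
#' @param candidates `"random"` or `"cnn"` (requires `scorer`).
#' @param setup_objective blocking objective, or `"none"`.
#' @param n_beams candidate beams.
#' @param seed integer seed for this run.
#' @param scorer a `beam_scorer` (for `candidates = "cnn"` and/or `"BCW"`
#'   on random candidates).
#' @param schedule [anneal_schedule()] for the setup search (its seed is
#'   re-derived from `seed`).
#' @param lift_offsets LIFT offsets (1 or 3 angles).
#' @param bstar use the weighted-subset pose search (B*).
#' @param two_stage also run the MU-minimization stage.
#' @param viewports optional precomputed [viewport_map()].
#' @param margin blocking margin, mm.
#' @return A `sono_workflow` list: `plan1`, `plan2` (or NULL), `beams`,
#'   `kept` (surviving beam indices), `blocked`, `setup`
#'   ([anneal_result] or NULL), `baseline_plan1` (no-robot plan when one
#'   was computed), and the run metadata.
#' @export
run_workflow <- function(bundle, candidates = c("random", "cnn"),
                         setup_objective = c("none", "BR", "BRW", "BC", "BCW"),
                         n_beams = 500, seed = 1L, scorer = NULL,
                         schedule = anneal_schedule(),
                         lift_offsets = 0, bstar = FALSE, two_stage = TRUE,
                         viewports = NULL, margin = 20) {
  candidates <- match.arg(candidates)
  setup_objective <- match.arg(setup_objective)
  beams <- if (candidates == "cnn") {
    if (is.null(scorer)) abort("cnn candidates require a scorer")
    sample_cnn_beams(scorer, bundle$ct, bundle$structures, bundle$grid,
                     n_beams, seed = derive_seed(seed, 11L))
  } else {
    sample_candidate_beams(bundle$grid, n_beams, seed = derive_seed(seed, 11L))
  }
  D <- compute_dose_matrix(bundle$ct, bundle$grid, beams)

  setup <- NULL
  blocked <- integer(0)
  baseline_plan1 <- NULL
  if (setup_objective != "none") {
    weights <- switch(setup_objective,
      BR = , BC = rep(1, nrow(beams)),
      BRW = {
        baseline_plan1 <- optimize_coverage(D, bundle$constraints)
        baseline_plan1$weights
      },
      BCW = {
        if (candidates == "cnn") {
          beams$weight_mu
        } else {
          if (is.null(scorer)) abort("BCW on random candidates needs a scorer")
          predict_weight(scorer, beam_features(bundle$ct, bundle$structures,
                                               beams, scorer$fspec,
                                               labels = bundle$labels,
                                               centroid = bundle$centroid))
        }
      })
    vps <- viewports %||% viewport_map(bundle$ct, bundle$grid)
    sched <- schedule
    sched$seed <- derive_seed(seed, 23L)
    if (bstar) {
      sub <- which(weights > 1e-9)
      if (length(sub) == 0) abort("B* pose search needs weighted beams")
      ospec <- objective_spec(setup_objective,
                              beams[sub, , drop = FALSE], weights[sub])
    } else {
      ospec <- objective_spec(setup_objective, beams, weights)
    }
    setup <- optimize_setup(ospec, vps, bundle$centroid, sched,
                            lift_offsets = lift_offsets, margin = margin)
    blocked <- blocked_set(beams, setup$best_state, vps, bundle$centroid,
                           lift_offsets, margin)
  }

  kept <- setdiff(seq_len(nrow(beams)), blocked)
  if (length(kept) == 0) abort("all candidate beams are blocked")
  Dk <- D
  Dk$D <- D$D[, kept, drop = FALSE]
  plan1 <- optimize_coverage(Dk, bundle$constraints)
  plan2 <- if (two_stage) optimize_mu(Dk, bundle$constraints, plan1) else NULL

  structure(list(
    plan1 = plan1, plan2 = plan2, beams = beams, kept = kept,
    blocked = blocked, setup = setup, baseline_plan1 = baseline_plan1,
    candidates = candidates, setup_objective = setup_objective,
    lift_offsets = lift_offsets, bstar = bstar, seed = seed),
    class = "sono_workflow")
}

#' @export
print.sono_workflow <- function(x, ...) {
  cat(sprintf(
    "<sono_workflow> %s candidates, objective %s%s: %d/%d beams blocked\n",
    x$candidates, x$setup_objective, if (x$bstar) " (B*)" else "",
    length(x$blocked), nrow(x$beams)))
  print(x$plan1)
  if (!is.null(x$plan2)) print(x$plan2)
  invisible(x)
}
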