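#' Annealing schedule
#'
#' Geometric cooling: the temperature starts at `theta0 = 10` and is
#' halved every 100 iterations; 1000 iterations per run, with the run
#' repeated from 5 random initial states and the best state kept.
#'
#' @param theta0 initial temperature.
#' @param halve_every iterations between halvings.
#' @param iterations iterations per restart.
#' @param restarts number of random initial states.
#' @param seed master seed (each restart derives its own).
#' @return An `anneal_schedule` list.
#' @export
anneal_schedule <- function(theta0 = 10, halve_every = 100,
                            iterations = 1000, restarts = 5, seed = 1L) {
  stopifnot(theta0 > 0, halve_every > 0, iterations > 0, restarts > 0)
  structure(list(theta0 = theta0, halve_every = halve_every,
                 iterations = iterations, restarts = restarts,
                 seed = as.integer(seed)),
            class = "anneal_schedule")
}

#' Simulated annealing over an abstract problem
#'
#' Metropolis acceptance: improving moves are always accepted, a worsening
#' move with probability `exp(-delta / theta)`. The `problem` is a list of
#' three closures sharing the ambient RNG: `random_state()`,
#' `neighbor(state, theta)` and `objective(state)` (`Inf` marks an
#' infeasible state).
#'
#' @param problem problem definition (see above).
#' @param schedule an [anneal_schedule()].
#' @return An `anneal_result`: `best_state`, `best_objective`, `trace`
#'   tibble (restart, iteration, theta, objective, best, accepted).
#' @export
anneal <- function(problem, schedule = anneal_schedule()) {
  best_state <- NULL
  best_obj <- Inf
  traces <- list()
  for (r in seq_len(schedule$restarts)) {
    tr <- with_seed(derive_seed(schedule$seed, r), {
      state <- problem$random_state()
      obj <- problem$objective(state)
      if (!is.finite(obj)) {
        for (k in 1:50) {
          state <- problem$random_state()
          obj <- problem$objective(state)
          if (is.finite(obj)) break
        }
        if (!is.finite(obj)) abort("no feasible initial state found")
      }
      run_best <- obj
      run_best_state <- state
      rows <- matrix(NA_real_, schedule$iterations, 4)
      for (it in seq_len(schedule$iterations)) {
        theta <- schedule$theta0 / 2^((it - 1) %/% schedule$halve_every)
        cand <- problem$neighbor(state, theta)
        cobj <- problem$objective(cand)
        acc <- is.finite(cobj) &&
          (cobj <= obj || runif(1) < exp(-(cobj - obj) / theta))
        if (acc) {
          state <- cand
          obj <- cobj
          if (obj < run_best) {
            run_best <- obj
            run_best_state <- state
          }
        }
        rows[it, ] <- c(theta, obj, run_best, acc)
      }
      list(rows = rows, best = run_best, state = run_best_state)
    })
    traces[[r]] <- tibble(restart = r, iteration = seq_len(schedule$iterations),
                          theta = tr$rows[, 1], objective = tr$rows[, 2],
                          best = tr$rows[, 3], accepted = tr$rows[, 4] > 0)
    if (tr$best < best_obj) {
      best_obj <- tr$best
      best_state <- tr$state
    }
  }
  structure(list(best_state = best_state, best_objective = best_obj,
                 trace = dplyr::bind_rows(traces), schedule = schedule),
            class = "anneal_result")
}

#' @export
print.anneal_result <- function(x, ...) {
  cat(sprintf("<anneal_result> best objective %.4g after %d restarts x %d iterations\n",
              x$best_objective, x$schedule$restarts,
              max(x$trace$iteration)))
  invisible(x)
}

#' Blocking objective specification
#'
#' The four setup objectives: the number of blocked randomly sampled beams
#' (`BR`), the summed plan weight of blocked randomly sampled beams
#' (`BRW`), the number of blocked scorer-generated beams (`BC`) and the
#' summed predicted weight of blocked scorer-generated beams (`BCW`).
#' `BR`/`BC` use implicit unit weights.
#'
#' @param kind one of `"BR"`, `"BRW"`, `"BC"`, `"BCW"`.
#' @param beams the candidate beam set the objective counts over.
#' @param weights per-beam weights (plan MU for BRW, predicted weight for
#'   BCW); ignored for BR/BC.
#' @return An `objective_spec`.
#' @export
objective_spec <- function(kind = c("BR", "BRW", "BC", "BCW"), beams,
                           weights = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("BR", "BC")) {
    weights <- rep(1, nrow(beams))
  } else {
    weights <- weights %||% beams$weight_mu
    if (is.null(weights) || anyNA(weights)) {
      abort("weighted objective needs per-beam weights")
    }
  }
  if (length(weights) != nrow(beams)) {
    abort("weights length must equal the beam count")
  }
  if (any(weights < 0)) abort("weights must be nonnegative")
  structure(list(kind = kind, beams = beams, weights = weights),
            class = "objective_spec")
}

#' Blocking objective value of a robot setup
#'
#' Sum of the objective weights over the beams blocked under the setup
#' (intersection over the LIFT angles); `Inf` for an infeasible setup.
#'
#' @param state a [robot_setup()].
#' @param spec an [objective_spec()].
#' @param viewports a [viewport_map()].
#' @param centroid target centroid (defaults to the map's).
#' @param lift_offsets LIFT offsets (see [blocked_set()]).
#' @param margin blocking margin, mm.
#' @return Scalar objective (lower is better).
#' @export
setup_objective <- function(state, spec, viewports,
                            centroid = attr(viewports, "centroid"),
                            lift_offsets = 0, margin = 20) {
  bl <- tryCatch(
    blocked_set(spec$beams, state, viewports, centroid, lift_offsets, margin),
    error = function(e) NULL)
  if (is.null(bl)) return(Inf)
  sum(spec$weights[bl])
}

# uniform point in a box
runif_box <- function(box) {
  box$lo + runif(3) * (box$hi - box$lo)
}

#' Robot-setup search problem
#'
#' Builds the [anneal()] problem for the setup search over base position
#' (continuous within the allowed boxes), viewport, and LIFT angle. The
#' neighbourhood draws one of four moves with equal probability: Gaussian
#' base jitter (sigma 30 mm, clipped to the box), a switch to a uniform
#' position in another box, a jump to a feasible viewport within 25 mm
#' (with probability 0.1 a uniform feasible viewport), or Gaussian LIFT
#' jitter (sigma 15 deg). Moves are redrawn until the state is feasible
#' (at most 50 tries, then the input state is returned unchanged).
#'
#' @param spec an [objective_spec()].
#' @param viewports a [viewport_map()].
#' @param centroid target centroid, mm.
#' @param boxes named list of base boxes (see [default_base_boxes()]).
#' @param lift_offsets LIFT offsets applied to the state's angle.
#' @param margin blocking margin, mm.
#' @return A problem list for [anneal()].
#' @export
robot_setup_problem <- function(spec, viewports,
                                centroid = attr(viewports, "centroid"),
                                boxes = default_base_boxes(),
                                lift_offsets = 0, margin = 20) {
  feas_idx <- which(viewports$feasible)
  if (length(feas_idx) == 0) abort("viewport map has no feasible viewport")
  vp_xyz <- as.matrix(viewports[, c("x", "y", "z")])

  feasible <- function(state) {
    is.finite(setup_objective(state, minimal_spec, viewports, centroid,
                              lift_offsets, margin))
  }
  # feasibility only needs a solvable configuration, not the blocking sum
  minimal_spec <- objective_spec("BR", spec$beams[1, , drop = FALSE])

  random_state <- function() {
    bx <- sample(names(boxes), 1)
    robot_setup(runif_box(boxes[[bx]]), bx,
                feas_idx[sample.int(length(feas_idx), 1)],
                runif(1, -pi, pi))
  }

  neighbor <- function(state, theta) {
    for (try in 1:50) {
      cand <- state
      move <- sample.int(4, 1)
      if (move == 1) {
        box <- boxes[[state$box]]
        cand$base_position <- pmin(pmax(state$base_position + rnorm(3, 0, 30),
                                        box$lo), box$hi)
      } else if (move == 2) {
        bx <- sample(names(boxes), 1)
        cand$box <- bx
        cand$base_position <- runif_box(boxes[[bx]])
      } else if (move == 3) {
        if (runif(1) < 0.1 || length(feas_idx) == 1) {
          cand$viewport_index <- feas_idx[sample.int(length(feas_idx), 1)]
        } else {
          here <- vp_xyz[state$viewport_index, ]
          d2 <- rowSums(sweep(vp_xyz[feas_idx, , drop = FALSE], 2, here)^2)
          near <- feas_idx[d2 <= 25^2]
          cand$viewport_index <- near[sample.int(length(near), 1)]
        }
      } else {
        cand$lift <- state$lift + rnorm(1, 0, pi / 12)
      }
      if (feasible(cand)) return(cand)
    }
    state
  }

  list(random_state = random_state,
       neighbor = neighbor,
       objective = function(state) {
         setup_objective(state, spec, viewports, centroid, lift_offsets,
                         margin)
       })
}

#' Optimize the robot setup
#'
#' Simulated annealing over [robot_setup_problem()] under the chosen
#' blocking objective.
#'
#' @inheritParams robot_setup_problem
#' @param schedule an [anneal_schedule()].
#' @return The [anneal()] result.
#' @export
optimize_setup <- function(spec, viewports,
                           centroid = attr(viewports, "centroid"),
                           schedule = anneal_schedule(),
                           boxes = default_base_boxes(),
                           lift_offsets = 0, margin = 20) {
  problem <- robot_setup_problem(spec, viewports, centroid, boxes,
                                 lift_offsets, margin)
  anneal(problem, schedule)
}
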