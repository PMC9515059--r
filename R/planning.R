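#' Planning constraints
#'
#' Hard bounds of the inverse planning problem: 36.25 Gy prescription,
#' 40.25 / 36 Gy maximum doses for PTV / OARs, 300 MU per beam and
#' 40,000 MU total. Shell maxima are unconstrained (`Inf`) until set, e.g.
#' by [calibrate_shell_dose()].
#'
#' @param prescribed_dose prescription, Gy.
#' @param ptv_max,oar_max,shell3_max,shell9_max maximum doses, Gy.
#' @param beam_mu_max,total_mu_max activation-time caps, MU.
#' @return A `plan_constraints` list.
#' @export
plan_constraints <- function(prescribed_dose = 36.25, ptv_max = 40.25,
                             oar_max = 36, shell3_max = Inf, shell9_max = Inf,
                             beam_mu_max = 300, total_mu_max = 40000) {
  if (prescribed_dose > ptv_max) abort("prescribed_dose must be <= ptv_max")
  stopifnot(prescribed_dose > 0, oar_max > 0, beam_mu_max > 0,
            total_mu_max > 0)
  structure(list(prescribed_dose = prescribed_dose, ptv_max = ptv_max,
                 oar_max = oar_max, shell3_max = shell3_max,
                 shell9_max = shell9_max, beam_mu_max = beam_mu_max,
                 total_mu_max = total_mu_max),
            class = "plan_constraints")
}

# canonical sparse form for triplet extraction
as_dgc <- function(M) {
  methods::as(methods::as(methods::as(M, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

# per-row maximum dose from the region labels
row_caps <- function(region, c) {
  caps <- rep(Inf, length(region))
  caps[region == "PTV"] <- c$ptv_max
  caps[region %in% c("BLADDER", "RECTUM")] <- c$oar_max
  caps[region == "SHELL3"] <- c$shell3_max
  caps[region == "SHELL9"] <- c$shell9_max
  caps
}

# Solve min cc'x, rows A x (sense) b, bounds lo/hi via the bundled simplex.
# basis0: optional 1-based basic-column hint per row (0 = row slack).
# Larger instances get the solver's anti-degeneracy bound perturbation.
lp_solve <- function(A, b, sense, cc, lo, hi, basis0 = NULL,
                     perturb = nrow(A) >= 200) {
  .lp_solve_cpp(A, b, as.integer(sense), cc, lo, hi,
                if (!is.null(basis0)) as.integer(basis0), perturb = perturb)
}

new_treatment_plan <- function(weights, dose, region, constraints, stage,
                               solver = list()) {
  p <- constraints$prescribed_dose
  ptv <- region == "PTV"
  dose_ptv <- dose[ptv]
  structure(list(
    weights = weights,
    dose = dose,
    region = region,
    coverage = mean(dose_ptv >= p - 1e-9),
    total_mu = sum(weights),
    objective_underdose = sum(pmax(0, p - dose_ptv)),
    stage = stage,
    constraints = constraints,
    solver = solver), class = "treatment_plan")
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat(sprintf(
    "<treatment_plan> stage=%s: coverage %.2f%%, total %.0f MU, %d/%d beams, underdose %.3f Gy\n",
    x$stage, 100 * x$coverage, x$total_mu, sum(x$weights > 1e-9),
    length(x$weights), x$objective_underdose))
  invisible(x)
}

#' Stage 1: coverage optimization
#'
#' Maximizes PTV coverage through its linear surrogate — minimizing the
#' total underdosage `sum_i max(0, prescribed - d_i)` over PTV voxels —
#' subject to hard maximum-dose constraints on PTV, OARs and shells, the
#' 300 MU per-beam and 40,000 MU total caps. Solved as an LP
#' (`min sum u_i` with `u_i >= prescribed - d_i`, `u_i >= 0`) by the
#' bundled simplex behind a row-generation loop: only violated dose rows
#' enter the working set, which keeps the solved LPs small. Coverage is a
#' counting quantity and is evaluated post hoc, never part of the LP.
#'
#' @param D a `dose_matrix` from [compute_dose_matrix()].
#' @param constraints a [plan_constraints()].
#' @return A `treatment_plan` (stage `"coverage"`).
#' @export
optimize_coverage <- function(D, constraints = plan_constraints()) {
  region <- D$region
  if (!any(region == "PTV")) abort("dose matrix has no PTV rows")
  if (lp_backend() == "highs") stage1_sparse(D, constraints)
  else stage1_rowgen(D, constraints)
}

# one-shot sparse formulation for the HiGHS backend
stage1_sparse <- function(D, constraints) {
  M <- as_dgc(D$D)
  region <- D$region
  nb <- ncol(M)
  p <- constraints$prescribed_dose
  caps <- row_caps(region, constraints)
  ptv <- which(region == "PTV")
  # a cap row can only bind if it is reachable even with every beam at the
  # per-beam maximum; unreachable rows are dropped from the LP up front
  dose_ub <- constraints$beam_mu_max * Matrix::rowSums(M)
  capr <- which(is.finite(caps) & dose_ub > caps)
  nu <- length(ptv)
  nc <- length(capr)
  tri <- Matrix::summary(M)
  posu <- integer(nrow(M)); posu[ptv] <- seq_len(nu)
  posc <- integer(nrow(M)); posc[capr] <- seq_len(nc)
  su <- posu[tri$i] > 0
  sc <- posc[tri$i] > 0
  ai <- c(posu[tri$i[su]],                      # underdose block
          rep(nu + 1L, nb),                     # total-MU row
          nu + 1L + posc[tri$i[sc]],            # cap block
          seq_len(nu))                          # u identity
  aj <- c(tri$j[su], seq_len(nb), tri$j[sc], nb + seq_len(nu))
  ax <- c(tri$x[su], rep(1, nb), tri$x[sc], rep(1, nu))
  m <- nu + 1L + nc
  n <- nb + nu
  r <- lp_solve_sparse(ai, aj, ax, m, n,
                       b = c(rep(p, nu), constraints$total_mu_max, caps[capr]),
                       sense = c(rep(1L, nu), rep(-1L, nc + 1L)),
                       cc = c(rep(0, nb), rep(1, nu)),
                       lo = rep(0, n),
                       hi = c(rep(constraints$beam_mu_max, nb), rep(Inf, nu)))
  if (r$status != "optimal") {
    abort(paste0("stage-1 LP not solved to optimality (", r$status,
                 "); binding bounds: per-beam ", constraints$beam_mu_max,
                 " MU, total ", constraints$total_mu_max, " MU"))
  }
  w <- pmin(pmax(r$x[1:nb], 0), constraints$beam_mu_max)
  new_treatment_plan(w, as.numeric(M %*% w), region, constraints, "coverage",
                     list(backend = "highs", rows = m))
}

# row-generation loop around the bundled dense simplex
stage1_rowgen <- function(D, constraints) {
  region <- D$region
  M <- D$D
  nb <- ncol(M)
  ptv_rows <- which(region == "PTV")
  p <- constraints$prescribed_dose
  caps <- row_caps(region, constraints)

  U <- ptv_rows  # underdose rows: all violated at w = 0, so all enter
  C <- integer(0)  # active maximum-dose rows
  w <- rep(0, nb)
  iters <- 0L
  for (outer in 1:40) {
    m <- length(U) + length(C) + 1L
    n <- nb + length(U)
    A <- matrix(0, m, n)
    A[seq_along(U), 1:nb] <- as.matrix(M[U, , drop = FALSE])
    A[cbind(seq_along(U), nb + seq_along(U))] <- 1
    A[length(U) + 1L, 1:nb] <- 1
    if (length(C)) {
      A[length(U) + 1L + seq_along(C), 1:nb] <- as.matrix(M[C, , drop = FALSE])
    }
    b <- c(rep(p, length(U)), constraints$total_mu_max, caps[C])
    sense <- c(rep(1L, length(U)), -1L, rep(-1L, length(C)))
    cc <- c(rep(0, nb), rep(1, length(U)))
    lo <- rep(0, n)
    hi <- c(rep(constraints$beam_mu_max, nb), rep(Inf, length(U)))
    # primal-feasible start: w = 0, every u basic at the prescription,
    # cap/total slacks basic -- phase 1 is skipped entirely
    basis0 <- c(nb + seq_along(U), rep(0L, length(C) + 1L))
    r <- lp_solve(A, b, sense, cc, lo, hi, basis0)
    if (r$status != "optimal") {
      abort(paste0("stage-1 LP not solved to optimality (", r$status,
                   "); binding bounds: per-beam ", constraints$beam_mu_max,
                   " MU, total ", constraints$total_mu_max, " MU"))
    }
    iters <- iters + r$iterations
    w <- pmin(pmax(r$x[1:nb], 0), constraints$beam_mu_max)
    d <- as.numeric(M %*% w)
    cap_gap <- d - caps
    viol_c <- setdiff(which(cap_gap > 1e-7), C)
    if (length(viol_c) > 2048) {
      viol_c <- viol_c[order(cap_gap[viol_c], decreasing = TRUE)][1:2048]
    }
    if (length(viol_c) == 0) break
    C <- c(C, viol_c)
  }
  new_treatment_plan(w, d, region, constraints, "coverage",
                     list(backend = "simplex", iterations = iters,
                          outer = outer, rows = length(U) + length(C) + 1L))
}

#' Stage 2: MU minimization at fixed dose lower bounds
#'
#' Minimizes total MU while fixing per-voxel lower bounds on the PTV dose
#' at the stage-1 values, under the same hard maximum-dose constraints.
#' The stage-1 weights remain feasible, so coverage can never decrease and
#' total MU can never increase.
#'
#' @param D a `dose_matrix`.
#' @param constraints a [plan_constraints()]; must match stage 1.
#' @param plan1 the stage-1 `treatment_plan` on the same matrix.
#' @return A `treatment_plan` (stage `"mu"`).
#' @export
optimize_mu <- function(D, constraints, plan1) {
  if (!inherits(plan1, "treatment_plan")) abort("plan1 must be a treatment_plan")
  region <- D$region
  M <- D$D
  nb <- ncol(M)
  if (length(plan1$weights) != nb) abort("plan1 does not match this dose matrix")
  caps <- row_caps(region, constraints)
  dlo <- plan1$dose

  solve2 <- if (lp_backend() == "highs") stage2_sparse else stage2_rowgen
  r <- solve2(M, region, caps, dlo, constraints, plan1, relax = 0)
  if (r$status != "optimal") {
    r <- solve2(M, region, caps, dlo, constraints, plan1, relax = 1e-9)
  }
  if (r$status != "optimal") {
    abort(paste0("stage-2 LP infeasible even after relaxing the stage-1 dose ",
                 "lower bounds by 1e-9 (", r$status, ")"))
  }
  new_treatment_plan(r$w, r$d, region, constraints, "mu", r$solver)
}

stage2_sparse <- function(M, region, caps, dlo, constraints, plan1, relax) {
  M <- as_dgc(M)
  nb <- ncol(M)
  ptv <- which(region == "PTV" & dlo > 1e-12)
  dose_ub <- constraints$beam_mu_max * Matrix::rowSums(M)
  capr <- which(is.finite(caps) & dose_ub > caps)
  nu <- length(ptv)
  nc <- length(capr)
  tri <- Matrix::summary(M)
  posu <- integer(nrow(M)); posu[ptv] <- seq_len(nu)
  posc <- integer(nrow(M)); posc[capr] <- seq_len(nc)
  su <- posu[tri$i] > 0
  sc <- posc[tri$i] > 0
  ai <- c(posu[tri$i[su]], rep(nu + 1L, nb), nu + 1L + posc[tri$i[sc]])
  aj <- c(tri$j[su], seq_len(nb), tri$j[sc])
  ax <- c(tri$x[su], rep(1, nb), tri$x[sc])
  m <- nu + 1L + nc
  r <- lp_solve_sparse(ai, aj, ax, m, nb,
                       b = c(dlo[ptv] - relax, constraints$total_mu_max,
                             caps[capr]),
                       sense = c(rep(1L, nu), rep(-1L, nc + 1L)),
                       cc = rep(1, nb), lo = rep(0, nb),
                       hi = rep(constraints$beam_mu_max, nb))
  if (r$status != "optimal") return(list(status = r$status))
  w <- pmin(pmax(r$x, 0), constraints$beam_mu_max)
  list(status = "optimal", w = w, d = as.numeric(M %*% w),
       solver = list(backend = "highs", rows = m))
}

stage2_rowgen <- function(M, region, caps, dlo, constraints, plan1, relax) {
  nb <- ncol(M)
  ptv_rows <- which(region == "PTV")
  U <- integer(0)
  C <- integer(0)
  w <- plan1$weights
  iters <- 0L
  for (outer in 1:60) {
    m <- length(U) + length(C) + 1L
    A <- matrix(0, m, nb)
    if (length(U)) A[seq_along(U), ] <- as.matrix(M[U, , drop = FALSE])
    if (length(C)) {
      A[length(U) + seq_along(C), ] <- as.matrix(M[C, , drop = FALSE])
    }
    A[m, ] <- 1
    b <- c(dlo[U] - relax, caps[C], constraints$total_mu_max)
    sense <- c(rep(1L, length(U)), rep(-1L, length(C)), -1L)
    r <- lp_solve(A, b, sense, rep(1, nb), rep(0, nb),
                  rep(constraints$beam_mu_max, nb))
    if (r$status != "optimal") return(list(status = r$status))
    iters <- iters + r$iterations
    w <- pmin(pmax(r$x, 0), constraints$beam_mu_max)
    d <- as.numeric(M %*% w)
    gap_u <- dlo - relax - d
    viol_u <- setdiff(ptv_rows[gap_u[ptv_rows] > 1e-9], U)
    if (length(viol_u) > 2048) {
      viol_u <- viol_u[order(gap_u[viol_u], decreasing = TRUE)][1:2048]
    }
    cap_gap <- d - caps
    viol_c <- setdiff(which(cap_gap > 1e-7), C)
    if (length(viol_c) > 2048) {
      viol_c <- viol_c[order(cap_gap[viol_c], decreasing = TRUE)][1:2048]
    }
    if (length(viol_u) == 0 && length(viol_c) == 0) {
      return(list(status = "optimal", w = w, d = d,
                  solver = list(backend = "simplex", iterations = iters,
                                outer = outer, rows = m)))
    }
    U <- c(U, viol_u)
    C <- c(C, viol_c)
  }
  list(status = "row_generation_limit")
}

#' PTV coverage of a plan
#'
#' Fraction of PTV voxels receiving at least the prescription, with a fixed
#' 1e-9 Gy tolerance on the threshold comparison.
#'
#' @param plan a `treatment_plan`.
#' @param prescribed prescription, Gy (defaults to the plan's constraints).
#' @return Fraction in `[0, 1]`.
#' @export
coverage <- function(plan, prescribed = plan$constraints$prescribed_dose) {
  ptv <- plan$region == "PTV"
  if (!any(ptv)) abort("plan has no PTV voxels")
  mean(plan$dose[ptv] >= prescribed - 1e-9)
}

#' Calibrate shell maximum doses to 95% coverage
#'
#' Tunes the shell maximum doses so that the stage-1 coverage without an
#' ultrasound robot is the desired 95%. A single scale factor `s` is
#' bisected over base bounds `shell3 = s * prescribed` and
#' `shell9 = 0.6 * s * prescribed` (one knob keeps the per-phantom tuning
#' deterministic); the smallest tested `s` whose coverage reaches the
#' target is returned, stopping once the achieved coverage is within
#' 0.25 percentage points of the target or the iteration cap is reached.
#'
#' @param ct a [ct_volume].
#' @param grid planning grid from [voxelize()].
#' @param beams `candidate_beams`.
#' @param target_coverage desired stage-1 coverage (0.95).
#' @param constraints base [plan_constraints()].
#' @param dose optional precomputed `dose_matrix` (skips ray tracing).
#' @param max_iter bisection budget (12).
#' @return list with `shell3_max`, `shell9_max`, `scale`, `coverage`,
#'   `plan` (the stage-1 plan at the returned bounds), `trace` (tibble of
#'   tested scales) and `unconstrained` flag (TRUE when even unconstrained
#'   shells cannot reach the target, in which case the bounds are `Inf`).
#' @export
calibrate_shell_dose <- function(ct, grid, beams, target_coverage = 0.95,
                                 constraints = plan_constraints(),
                                 dose = NULL, max_iter = 12) {
  D <- dose %||% compute_dose_matrix(ct, grid, beams)
  p <- constraints$prescribed_dose
  base3 <- p
  base9 <- 0.6 * p
  has_shells <- any(D$region %in% c("SHELL3", "SHELL9"))
  eval_s <- function(s) {
    cs <- constraints
    cs$shell3_max <- s * base3
    cs$shell9_max <- s * base9
    optimize_coverage(D, cs)
  }
  if (!has_shells) {
    pl <- optimize_coverage(D, constraints)
    return(list(shell3_max = base3, shell9_max = base9, scale = 1,
                coverage = pl$coverage, plan = pl,
                trace = tibble(scale = 1, coverage = pl$coverage),
                unconstrained = FALSE))
  }
  pl_inf <- optimize_coverage(D, constraints)  # shells unconstrained
  if (pl_inf$coverage < target_coverage) {
    warn("target coverage unreachable even with unconstrained shells")
    return(list(shell3_max = Inf, shell9_max = Inf, scale = Inf,
                coverage = pl_inf$coverage, plan = pl_inf,
                trace = tibble(scale = Inf, coverage = pl_inf$coverage),
                unconstrained = TRUE))
  }
  trace <- list()
  best <- NULL
  lo <- 0
  hi <- 1
  used <- 0L
  repeat {  # make sure the upper bracket reaches the target
    pl_hi <- eval_s(hi)
    used <- used + 1L
    trace[[length(trace) + 1]] <- c(hi, pl_hi$coverage)
    if (pl_hi$coverage >= target_coverage) { best <- list(s = hi, pl = pl_hi); break }
    lo <- hi
    hi <- 2 * hi
    if (used >= max_iter || hi > 16) { best <- list(s = Inf, pl = pl_inf); break }
  }
  while (is.finite(best$s) && used < max_iter &&
         best$pl$coverage - target_coverage > 0.0025) {
    mid <- (lo + best$s) / 2
    pl_mid <- eval_s(mid)
    used <- used + 1L
    trace[[length(trace) + 1]] <- c(mid, pl_mid$coverage)
    if (pl_mid$coverage >= target_coverage) {
      best <- list(s = mid, pl = pl_mid)
    } else {
      lo <- mid
    }
  }
  tr <- do.call(rbind, trace)
  list(shell3_max = best$s * base3, shell9_max = best$s * base9,
       scale = best$s, coverage = best$pl$coverage, plan = best$pl,
       trace = tibble(scale = tr[, 1], coverage = tr[, 2]),
       unconstrained = !is.finite(best$s))
}

#' Attach plan weights to a beam set
#'
#' @param beams `candidate_beams`.
#' @param plan a `treatment_plan` computed on the same beams.
#' @return The beam tibble with `weight_mu` filled, provenance `"plan"`.
#' @export
plan_beams <- function(beams, plan) {
  if (nrow(beams) != length(plan$weights)) {
    abort("beam set and plan have different sizes")
  }
  beams$weight_mu <- plan$weights
  as_candidate_beams(beams, "plan")
}

#' Export a plan as JSON
#'
#' Constraints block, per-beam weights, coverage, total MU, solver metadata.
#' @param plan a `treatment_plan`.
#' @param path output path.
#' @export
write_plan_json <- function(plan, path) {
  jsonlite::write_json(list(
    stage = plan$stage,
    constraints = unclass(plan$constraints),
    coverage = plan$coverage,
    total_mu = plan$total_mu,
    objective_underdose = plan$objective_underdose,
    weights_mu = plan$weights,
    solver = plan$solver), path, auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(path)
}
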