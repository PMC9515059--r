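# Shared fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- force(expr)
  fixture_env[[name]]
}

# uniform water-equivalent box: 200 mm cube of gray `gray` in air padding
uniform_ct <- function(gray = 1000, spacing = 5) {
  n <- round(200 / spacing) + 1
  pad <- 2
  d <- n + 2 * pad
  v <- array(0, dim = c(d, d, d))
  v[(pad + 1):(pad + n), (pad + 1):(pad + n), (pad + 1):(pad + n)] <- gray
  ct_volume(v, spacing = rep(spacing, 3),
            origin = rep(-spacing * (pad + (n - 1) / 2), 3))
}

# default phantom at coarse test resolution; reused across files
test_bundle <- function() {
  fixture("bundle5", prepare_phantom(phantom_spec(), resolution = 5,
                                     shell_scale = 1.3))
}

test_phantom <- function() {
  fixture("phantom", generate_phantom(phantom_spec()))
}

test_viewports <- function() {
  fixture("viewports", {
    bd <- test_bundle()
    viewport_map(bd$ct, bd$grid)
  })
}

# small random planning instances for LP contract tests: nv voxels of mixed
# regions, nb beams, dense nonnegative dose coefficients
random_instance <- function(seed, nb = 5, nv = 30, p_zero = 0.3) {
  with_seed(seed, {
    regions <- factor(
      sample(c("PTV", "BLADDER", "SHELL3"), nv, replace = TRUE,
             prob = c(0.5, 0.25, 0.25)),
      levels = c("PTV", "BLADDER", "RECTUM", "SHELL3", "SHELL9"))
    if (!any(regions == "PTV")) regions[1] <- "PTV"
    M <- matrix(round(runif(nv * nb), 3), nv, nb)
    M[runif(nv * nb) < p_zero] <- 0
    D <- structure(list(D = Matrix::Matrix(M, sparse = TRUE),
                        region = regions, n_beams = nb),
                   class = "dose_matrix")
    cs <- plan_constraints(
      prescribed_dose = 36.25, ptv_max = runif(1, 41, 60),
      oar_max = runif(1, 20, 40),
      shell3_max = runif(1, 20, 40), shell9_max = Inf,
      beam_mu_max = 300, total_mu_max = runif(1, 500, 4000))
    list(D = D, constraints = cs)
  })
}

# independent stage-1 formulation solved with pracma::linprog:
#   min sum(u)  s.t.  -Dw - u <= -p (PTV), Dw <= caps, sum w <= total,
#   0 <= w <= 300 via explicit rows (linprog has no upper bounds)
oracle_stage1 <- function(D, cs) {
  M <- as.matrix(D$D)
  region <- D$region
  nb <- ncol(M)
  ptv <- which(region == "PTV")
  nu <- length(ptv)
  caps <- rep(Inf, nrow(M))
  caps[region == "PTV"] <- cs$ptv_max
  caps[region %in% c("BLADDER", "RECTUM")] <- cs$oar_max
  caps[region == "SHELL3"] <- cs$shell3_max
  caps[region == "SHELL9"] <- cs$shell9_max
  capr <- which(is.finite(caps))
  n <- nb + nu
  A <- rbind(
    cbind(-M[ptv, , drop = FALSE], -diag(nu)),            # u >= p - Dw
    cbind(M[capr, , drop = FALSE], matrix(0, length(capr), nu)),
    c(rep(1, nb), rep(0, nu)),                            # total MU
    cbind(diag(nb), matrix(0, nb, nu)))                   # w <= 300
  b <- c(rep(-cs$prescribed_dose, nu), caps[capr], cs$total_mu_max,
         rep(cs$beam_mu_max, nb))
  r <- pracma::linprog(cc = c(rep(0, nb), rep(1, nu)), A = A, b = b,
                       maxiter = 2000)
  r
}

# brute-force ray-cast blocking oracle: sample `nray` rays inside the beam
# cone; blocked iff any ray comes within capsule radius + margin of a capsule
oracle_blocked <- function(beam, capsules, margin = 20, sad = 800,
                           nray = 500, seed = 1) {
  src <- c(beam$sx, beam$sy, beam$sz)
  tgt <- c(beam$tx, beam$ty, beam$tz)
  axis <- tgt - src
  len <- sqrt(sum(axis^2))
  axis <- axis / len
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u1 <- ref - sum(ref * axis) * axis
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(axis[2] * u1[3] - axis[3] * u1[2],
          axis[3] * u1[1] - axis[1] * u1[3],
          axis[1] * u1[2] - axis[2] * u1[1])
  rr <- beam$diameter_mm / 2 * (len / sad)  # cone radius at the target
  pts <- with_seed(seed, {
    th <- runif(nray, 0, 2 * pi)
    ra <- rr * sqrt(runif(nray))
    cbind(tgt[1] + ra * cos(th) * u1[1] + ra * sin(th) * u2[1],
          tgt[2] + ra * cos(th) * u1[2] + ra * sin(th) * u2[2],
          tgt[3] + ra * cos(th) * u1[3] + ra * sin(th) * u2[3])
  })
  for (k in seq_len(nrow(capsules$a))) {
    for (i in seq_len(nray)) {
      d <- .seg_seg_dist_cpp(src, pts[i, ], capsules$a[k, ], capsules$b[k, ])
      if (d < capsules$r[k] + margin) return(TRUE)
    }
  }
  FALSE
}

# random capsule set placed at a controlled clearance from a beam
random_capsules <- function(seed) {
  with_seed(seed, {
    a <- matrix(runif(6, -400, 400), 2)
    b <- a + matrix(rnorm(6, 0, 150), 2)
    structure(list(a = a, b = b, r = runif(2, 10, 60)),
              class = "capsule_set")
  })
}

# pure-R trilinear interpolation (independent of the C++ kernel)
tri_r <- function(ct, p) {
  d <- dim(ct$values)
  g <- (p - ct$origin) / ct$spacing
  if (any(g < -0.5) || any(g > d - 0.5)) return(0)
  g <- pmin(pmax(g, 0), d - 1)
  i0 <- pmin(floor(g), d - 2)
  i0[d == 1] <- 0
  f <- g - i0
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- pmin(i0 + c(dx, dy, dz), d - 1) + 1
    wgt <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
    val <- val + wgt * ct$values[ii[1], ii[2], ii[3]]
  }
  val
}

# independent R implementation of the documented pencil-cone dose model:
# midpoint-rule axis depth at step nodes, linear interpolation at the
# voxel's axis projection, exponential attenuation + inverse square
oracle_dose <- function(ct, vox, src, tgt, diam, mu = 0.005,
                        D0 = 36.25 / 300 * exp(mu * 100), sad = 800,
                        step = 1) {
  u <- (tgt - src) / sqrt(sum((tgt - src)^2))
  K <- ceiling(2 * sad / step)
  mids <- (seq_len(K) - 0.5) * step
  rho <- vapply(mids, function(t) {
    max(tri_r(ct, src + t * u), 0) / 1000
  }, 0)
  cum <- c(0, cumsum(rho * step))
  w <- vox - src
  t <- sum(w * u)
  if (t <= 0) return(0)
  dist <- sqrt(sum(w^2))
  lat2 <- dist^2 - t^2
  rcone <- diam / 2 * dist / sad
  if (lat2 > rcone^2) return(0)
  tk <- min(t / step, K - 1e-9)
  k0 <- floor(tk)
  rd <- cum[k0 + 1] + (tk - k0) * (cum[k0 + 2] - cum[k0 + 1])
  D0 * exp(-mu * rd) * (sad / dist)^2
}

# index-space annealing problem over a precomputed objective table
table_sa_problem <- function(tab) {
  dims <- dim(tab)
  list(
    table = tab,
    random_state = function() {
      vapply(dims, function(lim) sample.int(lim, 1), 0L)
    },
    neighbor = function(state, theta) {
      k <- sample.int(3, 1)
      lim <- dims[k]
      state[k] <- if (runif(1) < 0.2) {
        sample.int(lim, 1)
      } else {
        ((state[k] - 1L + sample(c(-1L, 1L), 1)) %% lim) + 1L
      }
      state
    },
    objective = function(state) tab[state[1], state[2], state[3]]
  )
}

# enumerable toy setup-search space: 10 base cells x 10 viewports x 8 LIFT
# angles, scored with the real summed-blocked-weight (BRW) objective of a
# stage-1 plan; the exhaustive minimum is the reference for SA recovery
toy_brw_problem <- function(n_base = 10, n_vp = 10, n_lift = 8) {
  fixture("toybrw", {
    bd <- test_bundle()
    vps <- test_viewports()
    beams <- sample_candidate_beams(bd$grid, 150, seed = 5)
    D <- compute_dose_matrix(bd$ct, bd$grid, beams)
    plan <- optimize_coverage(D, bd$constraints)
    spec <- objective_spec("BRW", beams, weights = plan$weights)
    feas <- which(vps$feasible)
    vp_idx <- feas[round(seq(1, length(feas), length.out = n_vp))]
    bx <- default_base_boxes()$legs
    tt <- seq(0.08, 0.92, length.out = n_base)
    cells <- t(vapply(tt, function(a) bx$lo + a * (bx$hi - bx$lo),
                      numeric(3)))
    lifts <- 2 * pi * (seq_len(n_lift) - 1) / n_lift - pi
    tab <- array(Inf, dim = c(n_base, n_vp, n_lift))
    for (i in seq_len(n_base)) {
      for (j in seq_len(n_vp)) {
        for (k in seq_len(n_lift)) {
          st <- robot_setup(cells[i, ], "legs", vp_idx[j], lifts[k])
          tab[i, j, k] <- setup_objective(st, spec, vps, bd$centroid)
        }
      }
    }
    table_sa_problem(tab)
  })
}
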