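test_that("transducer pose construction points and rolls correctly", {
  skin <- c(0, -90, 0)
  ctr <- c(0, 0, 0)
  # lateral base: roll points laterally
  pose <- transducer_pose_from_viewport(skin, ctr, c(300, -50, 0))
  expect_gt(sum(pose$roll * c(1, 0, 0)), 0)
  expect_equal(sum(pose$axial * (ctr - skin) / vnorm(ctr - skin)), 1,
               tolerance = 1e-9)
  # opposite bases give antiparallel rolls
  pose2 <- transducer_pose_from_viewport(skin, ctr, c(-300, -50, 0))
  expect_equal(sum(pose$roll * pose2$roll), -1, tolerance = 1e-9)
  # random geometry: roll is a unit vector orthogonal to the axial axis
  with_seed(5, {
    for (k in 1:25) {
      p <- transducer_pose_from_viewport(runif(3, -100, 100),
                                         runif(3, -20, 20),
                                         runif(3, -500, 500))
      expect_lt(abs(sum(p$roll * p$axial)), 1e-9)
      expect_equal(vnorm(p$roll), 1, tolerance = 1e-9)
    }
  })
  # collinear base falls back and is flagged
  pd <- transducer_pose_from_viewport(skin, ctr, skin + 5 * (skin - ctr))
  expect_true(pd$degenerate)
  expect_lt(abs(sum(pd$roll * pd$axial)), 1e-9)
})

test_that("capsule chain solves on the elbow circle with correct reach", {
  ctr <- c(0, 0, 0)
  pose <- transducer_pose_from_viewport(c(0, -90, 0), ctr, c(400, 0, 0))
  probe_len <- 80
  mount <- pose$position - probe_len * pose$axial
  # at full reach the elbow circle degenerates to a point
  dirv <- c(1, 0, 0)
  base_at <- function(d) mount - d * dirv
  c1 <- solve_configuration(base_at(920), pose, 0)
  c2 <- solve_configuration(base_at(920), pose, 2.1)
  expect_false(is.null(c1))
  expect_equal(c1$a[2, ], c2$a[2, ], tolerance = 1e-6)  # unique elbow
  # beyond reach / under minimum: infeasible
  expect_null(solve_configuration(base_at(921), pose, 0))
  expect_null(solve_configuration(base_at(149), pose, 0))
  # chain connects base to the transducer position
  cfg <- solve_configuration(base_at(600), pose, 1.2)
  expect_equal(cfg$a[1, ], base_at(600), tolerance = 1e-9)
  expect_equal(cfg$b[4, ], pose$position, tolerance = 1e-9)
  expect_equal(vnorm(cfg$b[1, ] - cfg$a[1, ]), 400, tolerance = 1e-6)
  expect_equal(vnorm(cfg$b[2, ] - cfg$a[2, ]), 400, tolerance = 1e-6)
  # LIFT is 2*pi periodic
  ca <- solve_configuration(base_at(600), pose, 0.7)
  cb <- solve_configuration(base_at(600), pose, 0.7 + 2 * pi)
  expect_equal(ca$a, cb$a, tolerance = 1e-9)
})

test_that("beam blocking matches trivial clearance cases", {
  beams <- sonoplan:::as_candidate_beams(
    tibble::tibble(id = 1L, sx = 0, sy = -800, sz = 0, tx = 0, ty = 0,
                   tz = 0, diameter_mm = 20, weight_mu = NA_real_), "random")
  far <- structure(list(a = matrix(c(500, 0, 0), 1), b = matrix(c(700, 0, 0), 1),
                        r = 30), class = "capsule_set")
  expect_false(beam_blocked(beams, far))
  crossing <- structure(list(a = matrix(c(-100, -400, 0), 1),
                             b = matrix(c(100, -400, 0), 1), r = 30),
                        class = "capsule_set")
  expect_true(beam_blocked(beams, crossing))
})

test_that("clearance blocking agrees with the ray-cast oracle", {
  n <- 250
  agree <- 0
  boundary_ok <- TRUE
  with_seed(77, {
    for (k in 1:n) {
      beam <- tibble::tibble(
        id = 1L, sx = runif(1, -800, 800), sy = runif(1, -800, -300),
        sz = runif(1, -400, 400), tx = runif(1, -30, 30),
        ty = runif(1, -30, 30), tz = runif(1, -30, 30),
        diameter_mm = sample(iris_diameters, 1), weight_mu = NA_real_)
      caps <- random_capsules(k)
      mine <- beam_blocked(sonoplan:::as_candidate_beams(beam, "random"),
                           caps)
      orac <- oracle_blocked(beam, caps, seed = k)
      if (mine == orac) {
        agree <- agree + 1
      } else {
        slack <- beam_clearance(sonoplan:::as_candidate_beams(beam, "random"),
                                caps)
        if (abs(slack) > 0.5) boundary_ok <- FALSE
      }
    }
  })
  expect_gte(agree / n, 0.99)
  expect_true(boundary_ok)
})

test_that("blocking is margin-monotone and rigid-motion invariant", {
  with_seed(12, {
    for (k in 1:20) {
      beam <- tibble::tibble(
        id = 1L, sx = runif(1, -600, 600), sy = -800, sz = runif(1, -300, 300),
        tx = 0, ty = 0, tz = 0, diameter_mm = 20, weight_mu = NA_real_)
      bt <- sonoplan:::as_candidate_beams(beam, "random")
      caps <- random_capsules(300 + k)
      m1 <- beam_blocked(bt, caps, margin = 10)
      m2 <- beam_blocked(bt, caps, margin = 40)
      expect_true(!m1 || m2)  # blocked(10) subset blocked(40)
      # joint rigid translation leaves the decision unchanged
      sh <- runif(3, -200, 200)
      beam2 <- beam
      beam2[, c("sx", "tx")] <- beam2[, c("sx", "tx")] + sh[1]
      beam2[, c("sy", "ty")] <- beam2[, c("sy", "ty")] + sh[2]
      beam2[, c("sz", "tz")] <- beam2[, c("sz", "tz")] + sh[3]
      caps2 <- caps
      caps2$a <- sweep(caps$a, 2, -sh)
      caps2$b <- sweep(caps$b, 2, -sh)
      expect_identical(
        beam_blocked(sonoplan:::as_candidate_beams(beam2, "random"), caps2),
        m1)
    }
  })
})

test_that("multi-LIFT blocking is the intersection over configurations", {
  bd <- test_bundle()
  vps <- test_viewports()
  beams <- sample_candidate_beams(bd$grid, 200, seed = 8)
  feas <- which(vps$feasible)
  with_seed(14, {
    checked <- 0
    for (k in 1:25) {
      bx <- default_base_boxes()$left
      st <- robot_setup(bx$lo + runif(3) * (bx$hi - bx$lo), "left",
                        sample(feas, 1), runif(1, -pi, pi))
      one <- tryCatch(blocked_set(beams, st, vps, bd$centroid, 0),
                      error = function(e) NULL)
      three <- tryCatch(
        blocked_set(beams, st, vps, bd$centroid, c(-pi / 6, 0, pi / 6)),
        error = function(e) NULL)
      if (is.null(one) || is.null(three)) next
      checked <- checked + 1
      expect_true(all(three %in% one))
    }
    expect_gte(checked, 10)
  })
})

test_that("a beam blocked under one LIFT but clear under another is kept", {
  bd <- test_bundle()
  vps <- test_viewports()
  feas <- which(vps$feasible)
  beams <- sample_candidate_beams(bd$grid, 400, seed = 44)
  found <- FALSE
  with_seed(99, {
    for (k in 1:40) {
      bx <- default_base_boxes()$legs
      st <- robot_setup(bx$lo + runif(3) * (bx$hi - bx$lo), "legs",
                        sample(feas, 1), runif(1, -pi, pi))
      sets <- lapply(c(-pi / 6, 0, pi / 6), function(off) {
        tryCatch(blocked_set(beams, st, vps, bd$centroid, off),
                 error = function(e) NULL)
      })
      if (any(vapply(sets, is.null, TRUE))) next
      inter <- Reduce(intersect, sets)
      uni <- Reduce(union, sets)
      if (length(uni) > length(inter)) {
        found <- TRUE
        all3 <- blocked_set(beams, st, vps, bd$centroid,
                            c(-pi / 6, 0, pi / 6))
        expect_identical(all3, sort(inter))
        moved <- setdiff(uni, inter)
        expect_false(any(moved %in% all3))
        break
      }
    }
  })
  expect_true(found)
})
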