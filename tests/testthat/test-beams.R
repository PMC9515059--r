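test_that("candidate beam sampling respects its construction constraints", {
  bd <- test_bundle()
  expect_equal(nrow(sample_candidate_beams(bd$grid, 0)), 0)
  beams <- sample_candidate_beams(bd$grid, 1000, seed = 3)
  expect_equal(nrow(beams), 1000)
  # sources on the 800 mm sphere around the PTV centroid, outside the body
  ptv <- bd$grid[bd$grid$region == "PTV", ]
  ctr <- c(mean(ptv$x), mean(ptv$y), mean(ptv$z))
  src <- cbind(beams$sx, beams$sy, beams$sz)
  r <- sqrt(rowSums(sweep(src, 2, ctr)^2))
  expect_true(all(abs(r - 800) < 1e-6))
  body <- bd$structures$masks$BODY
  ii <- round(sweep(src, 2, bd$structures$origin) %*%
                diag(1 / bd$structures$spacing)) + 1
  inside <- ii[, 1] >= 1 & ii[, 1] <= dim(body)[1] &
    ii[, 2] >= 1 & ii[, 2] <= dim(body)[2] &
    ii[, 3] >= 1 & ii[, 3] <= dim(body)[3]
  expect_false(any(inside))  # 800 mm sphere clears the volume entirely
  # targets are PTV voxel centres
  key <- paste(beams$tx, beams$ty, beams$tz)
  expect_true(all(key %in% paste(ptv$x, ptv$y, ptv$z)))
  # accessibility cap: no posterior/table sources
  u <- sweep(src, 2, ctr) / 800
  expect_true(all(u[, 2] <= 0.25 + 1e-9))
  expect_true(all(u[, 3] >= -0.5 - 1e-9))
  # determinism
  expect_identical(beams, sample_candidate_beams(bd$grid, 1000, seed = 3))
})

test_that("collimator diameters are uniform within multinomial bounds", {
  bd <- test_bundle()
  beams <- sample_candidate_beams(bd$grid, 6000, seed = 11)
  counts <- table(factor(beams$diameter_mm, levels = iris_diameters))
  expected <- 6000 / 5
  sigma <- sqrt(6000 * 0.2 * 0.8)
  expect_true(all(abs(counts - expected) < 3 * sigma))
})

test_that("radiological depth matches closed forms in layered media", {
  ct <- uniform_ct(1000)
  a <- c(-100, 0, 0); b <- c(0, 0, 0)
  expect_equal(radiological_depth(ct, a, b), 100, tolerance = 1e-9)
  # path entirely in air
  expect_equal(radiological_depth(ct, c(300, 300, 300), c(400, 300, 300)), 0)
  # half water, half bone (gray 2000): 50 * 1 + 50 * 2 = 150
  v <- ct$values
  half <- v
  d <- dim(v)
  xs <- ct$origin[1] + (seq_len(d[1]) - 1) * ct$spacing[1]
  half[xs > 0, , ] <- ifelse(v[xs > 0, , ] > 0, 2000, 0)
  ct2 <- ct_volume(half, ct$spacing, ct$origin)
  expect_equal(radiological_depth(ct2, c(-100, 0, 0), c(0, 0, 0)), 100,
               tolerance = 2)
  expect_equal(radiological_depth(ct2, c(0, 0, 0), c(100, 0, 0)), 200,
               tolerance = 4)
  expect_equal(radiological_depth(ct2, c(-100, 0, 0), c(100, 0, 0)), 300,
               tolerance = 4)
  expect_error(radiological_depth(ct, a, a), "degenerate")
})

test_that("radiological depth is additive along collinear points", {
  ph <- test_phantom()
  with_seed(42, {
    for (k in 1:20) {
      a <- runif(3, -150, 150)
      c_ <- runif(3, -150, 150)
      lam <- runif(1, 0.2, 0.8)
      b <- a + lam * (c_ - a)
      full <- radiological_depth(ph$ct, a, c_)
      parts <- radiological_depth(ph$ct, a, b) +
        radiological_depth(ph$ct, b, c_)
      expect_lt(abs(full - parts), 2 * 1)  # within 2 steps
    }
  })
})

test_that("dose matrix matches the independent R dose-model oracle", {
  ph <- test_phantom()
  grid <- voxelize(ph$structures, 5)
  beams <- sample_candidate_beams(grid, 8, seed = 5)
  D <- compute_dose_matrix(ph$ct, grid, beams, step = 2)
  M <- as.matrix(D$D)
  vox <- as.matrix(grid[, c("x", "y", "z")])
  with_seed(9, {
    rows <- sample.int(nrow(vox), 25)
    for (i in rows) {
      for (b in sample.int(8, 3)) {
        expected <- oracle_dose(ph$ct, vox[i, ],
                                c(beams$sx[b], beams$sy[b], beams$sz[b]),
                                c(beams$tx[b], beams$ty[b], beams$tz[b]),
                                beams$diameter_mm[b], step = 2)
        expect_equal(M[i, b], expected,
                     tolerance = 1e-6 * max(1e-12, abs(expected)))
      }
    }
  })
})

test_that("dose model definition holds on axis and off cone", {
  # homogeneous water block, beam along +x, entry at x = -100
  ct <- uniform_ct(1000)
  grid <- tibble::tibble(region = factor("PTV", levels = "PTV"),
                         x = c(-99.9, 0, 50), y = c(0, 0, 60), z = 0)
  beams <- sonoplan:::as_candidate_beams(
    tibble::tibble(id = 1L, sx = -900, sy = 0, sz = 0, tx = 0, ty = 0,
                   tz = 0, diameter_mm = 40, weight_mu = NA_real_), "random")
  D <- as.matrix(compute_dose_matrix(ct, grid, beams)$D)
  D0 <- 36.25 / 300 * exp(0.005 * 100)
  # on-axis voxel just past entry: dose ~ D0 at ~800 mm up to the couple of
  # water-equivalent mm the interpolated body edge contributes
  expect_equal(D[1, 1], D0 * (800 / 800.1)^2, tolerance = 0.03)
  # off-cone voxel receives nothing
  expect_equal(D[3, 1], 0)
  # depth dose falls monotonically along the axis in homogeneous tissue
  xs <- seq(-95, 95, by = 10)
  grid2 <- tibble::tibble(region = factor("PTV", levels = "PTV"),
                          x = xs, y = 0, z = 0)
  prof <- as.matrix(compute_dose_matrix(ct, grid2, beams)$D)[, 1]
  expect_true(all(diff(prof) < 0))
})

test_that("dose scales linearly with beam weight", {
  inst <- random_instance(3)
  w <- runif(inst$D$n_beams, 0, 100)
  d1 <- as.numeric(inst$D$D %*% w)
  d2 <- as.numeric(inst$D$D %*% (2 * w))
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("beam sets round-trip through CSV", {
  bd <- test_bundle()
  beams <- sample_candidate_beams(bd$grid, 20, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_beams_csv(beams, f)
  back <- read_beams_csv(f)
  expect_equal(back$sx, beams$sx, tolerance = 1e-9)
  expect_equal(back$diameter_mm, beams$diameter_mm)
})
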