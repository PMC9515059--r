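test_that("homogeneous phantom rasterizes to uniform tissue gray", {
  spec <- phantom_spec(bone_elements = list(), gas_pockets = list(),
                       bladder = list(center = c(0, -28, 42),
                                      semiaxes = c(26, 22, 26), gray = 1050),
                       rectum = list(center = c(0, 47, 5),
                                     semiaxes = c(14, 12, 55), gray = 1050),
                       spacing = 5)
  ph <- generate_phantom(spec)
  body <- ph$structures$masks$BODY
  expect_true(all(ph$ct$values[body] == spec$tissue_gray))
  expect_true(all(ph$ct$values[!body] == 0))
})

test_that("phantom generation is deterministic for a fixed spec", {
  spec <- phantom_spec(spacing = 5, noise_sd = 12, seed = 7L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$structures$masks, b$structures$masks)
})

test_that("gas spheres rasterize where geometry says", {
  spec <- phantom_spec(bone_elements = list(),
                       gas_pockets = list(list(center = c(0, -40, 0),
                                               radius = 10, gray = 50)),
                       spacing = 2.5)
  ph <- generate_phantom(spec)
  lat <- sonoplan:::phantom_lattice(spec)
  inside <- sonoplan:::rast_ellipsoid(lat, c(0, -40, 0), rep(10, 3))
  gas_mask <- ph$ct$values < 400 & ph$structures$masks$BODY
  expect_identical(which(gas_mask), which(inside & ph$structures$masks$BODY))
})

test_that("overlapping mandatory organs are rejected", {
  expect_error(
    generate_phantom(phantom_spec(
      rectum = list(center = c(0, 10, 0), semiaxes = c(20, 20, 30),
                    gray = 1040), spacing = 5)),
    "overlap")
})

test_that("shells are distance bands that exclude PTV and OARs", {
  ph <- test_phantom()
  st <- build_shells(ph$structures)
  for (nm in c("SHELL3", "SHELL9")) {
    expect_false(any(st$masks[[nm]] & st$masks$PTV))
    expect_false(any(st$masks[[nm]] & st$masks$BLADDER))
    expect_false(any(st$masks[[nm]] & st$masks$RECTUM))
  }
  expect_false(any(st$masks$SHELL3 & st$masks$SHELL9))

  # exhaustive distance-band oracle on the shell bounding region
  ptv_pts <- sonoplan:::mask_centers(st$masks$PTV, st$spacing, st$origin)
  check <- function(mask, lo, hi) {
    pts <- sonoplan:::mask_centers(mask, st$spacing, st$origin)
    take <- seq(1, nrow(pts), by = 17)  # spot-check a stratified subset
    for (i in take) {
      dmin <- sqrt(min(colSums((t(ptv_pts) - pts[i, ])^2)))
      expect_gt(dmin, lo)
      expect_lte(dmin, hi + 1e-9)
    }
  }
  check(st$masks$SHELL3, 0, 3)
  check(st$masks$SHELL9, 3, 9)
})

test_that("a single-voxel PTV gets its face neighbours as the 3 mm shell", {
  d <- c(9, 9, 9)
  ptv <- array(FALSE, d); ptv[5, 5, 5] <- TRUE
  st <- structure_set(list(PTV = ptv), spacing = c(3, 3, 3))
  out <- build_shells(st)
  idx <- which(out$masks$SHELL3, arr.ind = TRUE)
  expect_equal(nrow(idx), 6)  # centre-to-centre distance: face neighbours only
  expect_true(all(rowSums(abs(sweep(idx, 2, c(5, 5, 5)))) == 1))
  # zero distance list gives empty shells
  empty <- build_shells(st, distances = 0)
  expect_equal(sum(empty$masks$SHELL0), 0)
  expect_error(build_shells(structure_set(list(PTV = ptv & FALSE),
                                          spacing = c(3, 3, 3))),
               "empty")
})

test_that("spherical-PTV shell counts match the brute-force distance band", {
  d <- c(24, 24, 24)
  sp <- c(3, 3, 3)
  ctr <- c(34.5, 34.5, 34.5)
  coords <- as.matrix(expand.grid(x = (0:23) * 3, y = (0:23) * 3,
                                  z = (0:23) * 3))
  dist_ctr <- sqrt(rowSums(sweep(coords, 2, ctr)^2))
  ptv <- array(dist_ctr <= 15, dim = d)
  st <- build_shells(structure_set(list(PTV = ptv), spacing = sp))
  ptv_pts <- coords[ptv, , drop = FALSE]
  dmin <- apply(coords, 1, function(p) {
    sqrt(min(colSums((t(ptv_pts) - p)^2)))
  })
  expect_equal(sum(st$masks$SHELL9),
               sum(dmin > 3 & dmin <= 9))
  expect_equal(sum(st$masks$SHELL3), sum(dmin > 0 & dmin <= 3))
})

test_that("voxelize tiles an aligned cube exactly and matches a scan oracle", {
  d <- c(40, 40, 40)
  cube <- array(FALSE, d)
  cube[1:30, 1:30, 1:30] <- TRUE  # centres 0..29 mm at 1 mm spacing
  st <- structure_set(list(PTV = cube), spacing = c(1, 1, 1))
  grid <- voxelize(st, 3)
  expect_equal(sum(grid$region == "PTV"), 1000)

  # random ellipsoid: count equals brute-force centre-in-ellipsoid scan
  spec <- phantom_spec(spacing = 2.5)
  ph <- generate_phantom(spec)
  grid2 <- voxelize(ph$structures, 5)
  pts <- as.matrix(grid2[grid2$region == "PTV", c("x", "y", "z")])
  q <- sweep(pts, 2, spec$ptv_center)
  q <- sweep(q, 2, spec$ptv_semiaxes, `/`)
  expect_true(all(rowSums(q^2) <= 1 + 1e-9))
  # empty region gives no rows
  st2 <- structure_set(list(PTV = cube, BLADDER = cube & FALSE),
                       spacing = c(1, 1, 1))
  expect_equal(sum(voxelize(st2, 3)$region == "BLADDER"), 0)
})

test_that("region voxel lists are pairwise disjoint across random specs", {
  for (seed in seq(1, 100, by = 7)) {
    spec <- random_phantom_spec(seed, spacing = 5)
    ph <- generate_phantom(spec)
    grid <- voxelize(build_shells(ph$structures), 5)
    key <- paste(grid$x, grid$y, grid$z)
    expect_false(any(duplicated(key)))
  }
})

test_that("rasterization volume estimates are resolution-consistent", {
  spec_c <- phantom_spec(spacing = 4, bone_elements = list(),
                         gas_pockets = list())
  spec_f <- phantom_spec(spacing = 2, bone_elements = list(),
                         gas_pockets = list())
  vc <- sum(generate_phantom(spec_c)$structures$masks$PTV) * 4^3
  vf <- sum(generate_phantom(spec_f)$structures$masks$PTV) * 2^3
  expect_lt(abs(vc - vf) / vf, 0.05)
})

test_that("volumes and label masks round-trip through NIfTI", {
  ph <- test_phantom()
  f <- tempfile(fileext = ".nii.gz")
  write_ct_volume(ph$ct, f)
  back <- read_ct_volume(f, origin = ph$ct$origin)
  expect_equal(back$values, ph$ct$values, ignore_attr = TRUE)
  expect_equal(back$spacing, ph$ct$spacing, tolerance = 1e-6)
  f2 <- tempfile(fileext = ".nii.gz")
  write_structure_labels(ph$structures, f2, labels = c("PTV", "BLADDER"))
  st <- read_structure_labels(f2, c("PTV", "BLADDER"),
                              origin = ph$structures$origin)
  expect_identical(which(st$masks$PTV), which(ph$structures$masks$PTV))
})
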