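#' IRIS collimator diameters (mm)
#' @export
iris_diameters <- c(10, 15, 20, 30, 40)

#' Sample random candidate beams
#'
#' Sources are drawn uniformly on a spherical cap of the source sphere
#' (radius `sad`, centred at the PTV centroid) covering the
#' superior/anterior/lateral directions — the posterior (table) and
#' steep-inferior directions are excluded. Targets are drawn uniformly over
#' PTV voxel centres, collimator diameters uniformly over
#' [iris_diameters]. Deterministic per seed.
#'
#' @param grid planning grid tibble from [voxelize()] (needs PTV rows).
#' @param n number of beams (default 6000, the full-scale candidate count).
#' @param seed integer seed.
#' @param sad source-axis distance in mm (source sphere radius, 800).
#' @param cap_y_max,cap_z_min accessibility cap: unit source directions
#'   `u` (from the centroid) must satisfy `u_y <= cap_y_max` (not from the
#'   table side) and `u_z >= cap_z_min` (not from below).
#' @return A `candidate_beams` tibble: `id`, `sx sy sz`, `tx ty tz`,
#'   `diameter_mm`, `weight_mu` (NA until planned/predicted), with
#'   attribute `provenance = "random"`.
#' @export
sample_candidate_beams <- function(grid, n = 6000, seed = 1L, sad = 800,
                                   cap_y_max = 0.25, cap_z_min = -0.5) {
  ptv <- grid[grid$region == "PTV", , drop = FALSE]
  if (nrow(ptv) == 0) abort("planning grid has no PTV voxels")
  if (n < 0) abort("n must be nonnegative")
  centroid <- c(mean(ptv$x), mean(ptv$y), mean(ptv$z))
  if (n == 0) {
    out <- tibble(id = integer(), sx = numeric(), sy = numeric(),
                  sz = numeric(), tx = numeric(), ty = numeric(),
                  tz = numeric(), diameter_mm = numeric(),
                  weight_mu = numeric())
    return(as_candidate_beams(out, "random"))
  }
  with_seed(seed, {
    src <- matrix(NA_real_, n, 3)
    got <- 0L
    while (got < n) {
      m <- max(2L * (n - got), 64L)
      u <- matrix(rnorm(3 * m), m, 3)
      u <- u / sqrt(rowSums(u^2))
      ok <- u[, 2] <= cap_y_max & u[, 3] >= cap_z_min
      take <- min(sum(ok), n - got)
      if (take > 0) {
        src[(got + 1):(got + take), ] <- u[ok, , drop = FALSE][seq_len(take), ]
        got <- got + take
      }
    }
    src <- sweep(src * sad, 2, centroid, `+`)
    ti <- sample.int(nrow(ptv), n, replace = TRUE)
    out <- tibble(
      id = seq_len(n),
      sx = src[, 1], sy = src[, 2], sz = src[, 3],
      tx = ptv$x[ti], ty = ptv$y[ti], tz = ptv$z[ti],
      diameter_mm = sample(iris_diameters, n, replace = TRUE),
      weight_mu = NA_real_)
  })
  as_candidate_beams(out, "random")
}

as_candidate_beams <- function(x, provenance) {
  attr(x, "provenance") <- provenance
  class(x) <- unique(c("candidate_beams", class(x)))
  x
}

#' Read/write candidate beam sets as CSV
#'
#' Columns: `id, sx, sy, sz, tx, ty, tz, diameter_mm, weight_mu`.
#' @param beams a `candidate_beams` tibble.
#' @param path file path.
#' @export
write_beams_csv <- function(beams, path) {
  write.csv(as.data.frame(beams)[, c("id", "sx", "sy", "sz", "tx", "ty", "tz",
                                     "diameter_mm", "weight_mu")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beams_csv
#' @param provenance provenance tag to attach (`random`, `cnn` or `plan`).
#' @export
read_beams_csv <- function(path, provenance = "random") {
  as_candidate_beams(as_tibble(read.csv(path)), provenance)
}

#' Water-equivalent (radiological) path length
#'
#' Line integral of relative density `rho(gray) = max(gray / 1000, 0)`
#' along the segment from `a` to `b`, sampled with a fixed 1 mm step and
#' trilinear gray interpolation (midpoint rule; the final sub-step is
#' shortened to end exactly at `b`). Voxels outside the volume count as air.
#'
#' @param ct a [ct_volume].
#' @param a,b segment end points, mm.
#' @param step integration step, mm.
#' @return Water-equivalent depth in mm (nonnegative).
#' @export
radiological_depth <- function(ct, a, b, step = 1) {
  if (isTRUE(all.equal(a, b))) abort("degenerate ray: a == b")
  .rad_depth_cpp(ct$values, dim(ct$values), ct$spacing, ct$origin,
                 as.numeric(a), as.numeric(b), step)
}

#' Dose-per-MU matrix for a candidate beam set
#'
#' Pencil-cone dose model with exponential attenuation in water-equivalent
#' depth and inverse-square fall-off. A voxel centre `p` receives dose from
#' beam `b` iff it lies in front of the source within the cone of radius
#' `r(p) = (diameter / 2) * |p - source| / sad`; then
#' `d = D0 * exp(-mu * rd(t)) * (sad / |p - source|)^2` Gy per MU, where
#' `rd(t)` is the radiological depth from the source along the beam's
#' central axis (the pencil-beam convention), linearly interpolated at the
#' voxel's axis projection `t`.
#' `D0` is calibrated so a single 40 mm beam can deliver the
#' 36.25 Gy prescription to a PTV voxel at 100 mm water-equivalent depth on
#' the source sphere within the 300 MU per-beam cap:
#' `D0 = 36.25 / 300 * exp(mu * 100)`.
#'
#' The model is deliberately minimal but linear in beam weight — the
#' premise of the planning LP; it can be swapped by supplying a different
#' `dose_matrix` to the planners.
#'
#' @param ct a [ct_volume].
#' @param grid planning grid from [voxelize()].
#' @param beams `candidate_beams` tibble.
#' @param mu linear attenuation per water-equivalent mm (0.005).
#' @param sad source-axis distance, mm.
#' @param step ray-march step, mm.
#' @param D0 reference dose rate, Gy/MU.
#' @return A `dose_matrix` object: sparse `Matrix::dgCMatrix` (voxel rows x
#'   beam columns) with the grid's `region` factor attached.
#' @export
compute_dose_matrix <- function(ct, grid, beams, mu = 0.005, sad = 800,
                                step = 1, D0 = 36.25 / 300 * exp(mu * 100)) {
  if (nrow(beams) == 0) abort("beam set is empty")
  vox <- cbind(grid$x, grid$y, grid$z)
  tri <- .dose_matrix_cpp(ct$values, dim(ct$values), ct$spacing, ct$origin,
                          vox, cbind(beams$sx, beams$sy, beams$sz),
                          cbind(beams$tx, beams$ty, beams$tz),
                          beams$diameter_mm, mu, D0, sad, step)
  D <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                            dims = c(nrow(grid), nrow(beams)))
  structure(list(D = D, region = grid$region, n_beams = nrow(beams),
                 D0 = D0, mu = mu, sad = sad),
            class = "dose_matrix")
}

#' @export
print.dose_matrix <- function(x, ...) {
  cat("<dose_matrix> ", nrow(x$D), " voxels x ", ncol(x$D), " beams, ",
      length(x$D@x), " nonzeros\n", sep = "")
  invisible(x)
}

#' Write a dose matrix as plain-text sparse triplets
#'
#' MatrixMarket coordinate format plus a `<path>.regions.csv` sidecar with
#' the row regions.
#' @param dm a `dose_matrix`.
#' @param path base path for the `.mtx` file.
#' @export
write_dose_matrix <- function(dm, path) {
  Matrix::writeMM(dm$D, path)
  write.csv(data.frame(row = seq_along(dm$region), region = dm$region),
            paste0(path, ".regions.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_beams_csv
#' @export
write_beams_json <- function(beams, path) {
  jsonlite::write_json(list(
    provenance = attr(beams, "provenance"),
    beams = as.data.frame(beams)), path, auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(path)
}

#' @rdname write_beams_csv
#' @export
read_beams_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_candidate_beams(as_tibble(x$beams), x$provenance)
}
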