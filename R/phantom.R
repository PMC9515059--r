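#' Parametric pelvic phantom specification
#'
#' Describes a synthetic pelvic CT: an ellipsoidal body of soft tissue
#' containing an ellipsoidal prostate target (PTV), bladder
#' (anterior-superior) and rectum (posterior), plus bone primitives
#' (femoral heads / iliac wings as capsules) and optional bowel-gas
#' spheres. Gray values follow the offset-1000 convention (air 0,
#' water 1000, gray = HU + 1000), on which the ultrasound viewport
#' thresholds (gas < 400, dense > 1300) are coherent.
#'
#' @param body_semiaxes,body_center body ellipsoid, mm.
#' @param ptv_center,ptv_semiaxes target ellipsoid, mm. The default draws
#'   give volumes within the configured `ptv_volume_range`.
#' @param bladder,rectum lists with `center`, `semiaxes` (mm) and `gray`.
#' @param bone_elements list of capsules: `list(a =, b =, radius =, gray =)`.
#' @param gas_pockets list of spheres: `list(center =, radius =, gray =)`.
#' @param tissue_gray soft-tissue gray value (default 1050).
#' @param spacing native voxel spacing in mm (isotropic scalar or length 3).
#' @param noise_sd Gaussian gray noise inside the body (default 0, i.e.
#'   noiseless; CT texture modelling is out of scope).
#' @param seed integer seed used only for the optional noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_semiaxes = c(150, 95, 125),
                         body_center = c(0, 0, 0),
                         ptv_center = c(0, 5, 0),
                         ptv_semiaxes = c(21, 19, 23),
                         bladder = list(center = c(0, -28, 42),
                                        semiaxes = c(26, 22, 26), gray = 1010),
                         rectum = list(center = c(0, 47, 5),
                                       semiaxes = c(14, 12, 55), gray = 1040),
                         bone_elements = default_bones(),
                         gas_pockets = list(list(center = c(-8, 40, 28),
                                                 radius = 9, gray = 80)),
                         tissue_gray = 1050,
                         spacing = 2.5,
                         noise_sd = 0,
                         seed = 1L) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  spec <- structure(
    list(body_semiaxes = body_semiaxes, body_center = body_center,
         ptv_center = ptv_center, ptv_semiaxes = ptv_semiaxes,
         bladder = bladder, rectum = rectum,
         bone_elements = bone_elements, gas_pockets = gas_pockets,
         tissue_gray = tissue_gray, spacing = spacing,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

default_bones <- function() {
  list(
    list(a = c(-82, 10, -110), b = c(-78, 5, -10), radius = 14, gray = 1700),
    list(a = c(82, 10, -110), b = c(78, 5, -10), radius = 14, gray = 1700),
    list(a = c(-55, 28, 40), b = c(-95, 12, 100), radius = 12, gray = 1600),
    list(a = c(55, 28, 40), b = c(95, 12, 100), radius = 12, gray = 1600))
}

validate_phantom_spec <- function(spec) {
  inside_body <- function(p) {
    sum(((p - spec$body_center) / spec$body_semiaxes)^2) < 1
  }
  for (nm in c("ptv_center")) {
    if (!inside_body(spec[[nm]])) abort("PTV centre lies outside the body")
  }
  if (!inside_body(spec$bladder$center) || !inside_body(spec$rectum$center)) {
    abort("organ centre lies outside the body ellipsoid")
  }
  for (g in spec$gas_pockets) {
    if (g$gray >= 400) abort("gas gray value must be < 400")
  }
  for (b in spec$bone_elements) {
    if (b$gray <= 1300) abort("bone gray value must be > 1300")
  }
  greys <- c(spec$tissue_gray, spec$bladder$gray, spec$rectum$gray)
  if (any(greys < 400 | greys > 1300)) {
    abort("soft-tissue gray values must lie in [400, 1300]")
  }
  invisible(spec)
}

#' Draw a random phantom specification
#'
#' Jitters organ positions and sizes around the template of [phantom_spec()],
#' drawing the PTV volume uniformly within `ptv_volume_range` (the study
#' condition for prostate sizes) with mild anisotropy.
#'
#' @param seed integer seed; the draw is deterministic per seed.
#' @param ptv_volume_range target volume range in cm^3.
#' @param spacing native voxel spacing, mm.
#' @return A `phantom_spec`.
#' @export
random_phantom_spec <- function(seed, ptv_volume_range = c(25, 120),
                                spacing = 2.5) {
  with_seed(seed, {
    vol_cm3 <- runif(1, ptv_volume_range[1], ptv_volume_range[2])
    r0 <- (vol_cm3 * 1000 * 3 / (4 * pi))^(1 / 3)
    aniso <- runif(3, 0.85, 1.15)
    aniso <- aniso / prod(aniso)^(1 / 3)
    ptv_semi <- r0 * aniso
    ptv_c <- c(runif(1, -6, 6), runif(1, 0, 12), runif(1, -8, 8))
    bl_shift <- c(runif(1, -5, 5), runif(1, -6, 6), runif(1, -6, 6))
    re_shift <- c(runif(1, -4, 4), runif(1, -2, 8), runif(1, -6, 6))
    gap <- max(ptv_semi)
    phantom_spec(
      ptv_center = ptv_c,
      ptv_semiaxes = ptv_semi,
      bladder = list(center = c(0, -12, 18) + ptv_c +
                       c(0, -gap - 22, gap + 18) * c(0, 1, 1) + bl_shift,
                     semiaxes = runif(3, 20, 27), gray = 1010),
      rectum = list(center = c(0, 14, 0) + ptv_c + c(0, gap + 20, 0) + re_shift,
                    semiaxes = c(runif(1, 11, 14), runif(1, 10, 13),
                                 runif(1, 45, 60)), gray = 1040),
      gas_pockets = if (runif(1) < 0.7) {
        list(list(center = ptv_c + c(runif(1, -12, 12), gap + 16 + runif(1, 0, 6),
                                     runif(1, 18, 34)),
                  radius = runif(1, 6, 11), gray = 80))
      } else list(),
      spacing = spacing,
      seed = seed)
  })
}

# lattice voxel-centre coordinate vectors for a spec
phantom_lattice <- function(spec, margin = 2) {
  lo <- spec$body_center - spec$body_semiaxes - margin * spec$spacing
  hi <- spec$body_center + spec$body_semiaxes + margin * spec$spacing
  n <- ceiling((hi - lo) / spec$spacing) + 1
  list(x = lo[1] + (seq_len(n[1]) - 1) * spec$spacing[1],
       y = lo[2] + (seq_len(n[2]) - 1) * spec$spacing[2],
       z = lo[3] + (seq_len(n[3]) - 1) * spec$spacing[3],
       origin = lo, dim = as.integer(n))
}

# logical array of voxels inside an axis-aligned ellipsoid
rast_ellipsoid <- function(lat, center, semiaxes) {
  ex <- ((lat$x - center[1]) / semiaxes[1])^2
  ey <- ((lat$y - center[2]) / semiaxes[2])^2
  ez <- ((lat$z - center[3]) / semiaxes[3])^2
  q <- outer(outer(ex, ey, `+`), ez, `+`)
  q <= 1
}

# logical array of voxels within `radius` of segment a-b (capsule)
rast_capsule <- function(lat, a, b, radius) {
  d <- b - a
  len2 <- sum(d^2)
  gx <- array(lat$x, dim = c(length(lat$x), length(lat$y), length(lat$z)))
  gy <- aperm(array(lat$y, dim = c(length(lat$y), length(lat$x), length(lat$z))),
              c(2, 1, 3))
  gz <- aperm(array(lat$z, dim = c(length(lat$z), length(lat$x), length(lat$y))),
              c(2, 3, 1))
  tt <- ((gx - a[1]) * d[1] + (gy - a[2]) * d[2] + (gz - a[3]) * d[3]) /
    max(len2, 1e-12)
  tt <- pmin(pmax(tt, 0), 1)
  (gx - a[1] - tt * d[1])^2 + (gy - a[2] - tt * d[2])^2 +
    (gz - a[3] - tt * d[3])^2 <= radius^2
}

#' Generate a synthetic pelvic CT and structure set
#'
#' Rasterizes a [phantom_spec()] onto its voxel lattice. Gray assembly:
#' air (0) outside the body, soft tissue inside, organ gray values, then
#' bone and gas primitives override. Masks for PTV, bladder, rectum and
#' body are returned on the same lattice. Deterministic for a fixed spec
#' (the seed only drives optional noise).
#'
#' @param spec a `phantom_spec`.
#' @return list with elements `ct` ([ct_volume]) and `structures`
#'   ([structure_set]); the spec is attached as attribute `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  lat <- phantom_lattice(spec)
  body <- rast_ellipsoid(lat, spec$body_center, spec$body_semiaxes)
  ptv <- rast_ellipsoid(lat, spec$ptv_center, spec$ptv_semiaxes) & body
  bla <- rast_ellipsoid(lat, spec$bladder$center, spec$bladder$semiaxes) & body
  rec <- rast_ellipsoid(lat, spec$rectum$center, spec$rectum$semiaxes) & body
  if (sum(ptv) == 0) abort("PTV rasterized to an empty mask")
  if (any(ptv & bla) || any(ptv & rec) || any(bla & rec)) {
    abort(paste0("invalid phantom spec: PTV/bladder/rectum overlap after ",
                 "rasterization"))
  }
  gray <- array(0, dim = lat$dim)
  gray[body] <- spec$tissue_gray
  gray[bla] <- spec$bladder$gray
  gray[rec] <- spec$rectum$gray
  for (b in spec$bone_elements) {
    m <- rast_capsule(lat, b$a, b$b, b$radius) & body
    gray[m] <- b$gray
  }
  for (g in spec$gas_pockets) {
    m <- rast_ellipsoid(lat, g$center, rep(g$radius, 3)) & body
    gray[m] <- g$gray
  }
  if (spec$noise_sd > 0) {
    with_seed(spec$seed, {
      gray[body] <- gray[body] + rnorm(sum(body), 0, spec$noise_sd)
    })
  }
  ct <- ct_volume(gray, spacing = spec$spacing, origin = lat$origin)
  st <- structure_set(list(PTV = ptv, BLADDER = bla, RECTUM = rec, BODY = body),
                      spacing = spec$spacing, origin = lat$origin)
  structure(list(ct = ct, structures = st), spec = spec,
            class = "sono_phantom")
}

#' @export
print.sono_phantom <- function(x, ...) {
  cat("<sono_phantom>\n")
  print(x$ct)
  print(x$structures)
  invisible(x)
}

#' Build shell structures around the PTV
#'
#' Adds band structures `SHELL<d>` at the given distances from the target:
#' a voxel joins the band `(d_prev, d]` of its Euclidean distance to the
#' nearest PTV voxel centre. Shell voxels exclude the PTV and the OARs
#' (each voxel carries exactly one label, priority PTV > OAR > SHELL) and
#' are restricted to the body.
#'
#' @param structures a [structure_set] with a nonempty `PTV` mask.
#' @param distances increasing shell distances in mm (default `c(3, 9)`).
#' @return The structure set with `SHELL<d>` masks added.
#' @export
build_shells <- function(structures, distances = c(3, 9)) {
  ptv <- structures$masks$PTV
  if (is.null(ptv) || sum(ptv) == 0) abort("PTV mask is empty")
  distances <- sort(distances)
  masks <- structures$masks
  keepout <- ptv
  for (nm in c("BLADDER", "RECTUM")) {
    if (!is.null(masks[[nm]])) keepout <- keepout | masks[[nm]]
  }
  if (length(distances) == 0 || max(distances) <= 0) {
    for (d in distances) {
      masks[[paste0("SHELL", d)]] <- array(FALSE, dim = dim(ptv))
    }
    return(structure_set(masks, structures$spacing, structures$origin))
  }
  idx <- which(ptv, arr.ind = TRUE) - 1L
  dist <- .ptv_distance_cpp(idx, dim(ptv), structures$spacing, max(distances))
  dist <- array(dist, dim = dim(ptv))
  prev <- 0
  body <- masks$BODY
  for (d in distances) {
    band <- dist > prev & dist <= d & !keepout
    if (!is.null(body)) band <- band & body
    masks[[paste0("SHELL", d)]] <- band
    prev <- d
  }
  structure_set(masks, structures$spacing, structures$origin)
}

#' Discretize structures at planning resolution
#'
#' Resamples the structure masks onto a regular lattice (default 3 mm) of
#' voxel centres. A lattice cell takes the label of the region covering its
#' centre (nearest native voxel), with priority PTV > OAR > SHELL when
#' regions touch. The `BODY` mask is not part of the planning grid.
#'
#' @param structures a [structure_set].
#' @param resolution lattice spacing in mm (at least the native spacing).
#' @return A tibble with columns `region`, `x`, `y`, `z` (voxel centres in
#'   mm), one row per labelled lattice cell; attributes `resolution` and
#'   `regions`.
#' @export
voxelize <- function(structures, resolution = 3) {
  sp <- structures$spacing
  if (resolution < max(sp)) {
    abort("planning resolution must be at least the native voxel spacing")
  }
  d <- dim(structures$masks[[1]])
  org <- structures$origin
  ext <- org + (d - 1) * sp
  gx <- seq(org[1], ext[1], by = resolution)
  gy <- seq(org[2], ext[2], by = resolution)
  gz <- seq(org[3], ext[3], by = resolution)
  grid <- expand.grid(x = gx, y = gy, z = gz, KEEP.OUT.ATTRS = FALSE)
  ii <- round((grid$x - org[1]) / sp[1]) + 1L
  jj <- round((grid$y - org[2]) / sp[2]) + 1L
  kk <- round((grid$z - org[3]) / sp[3]) + 1L
  lin <- cbind(pmin(pmax(ii, 1L), d[1]), pmin(pmax(jj, 1L), d[2]),
               pmin(pmax(kk, 1L), d[3]))
  priority <- c("PTV", "BLADDER", "RECTUM",
                grep("^SHELL", names(structures$masks), value = TRUE))
  priority <- priority[priority %in% names(structures$masks)]
  region <- rep(NA_character_, nrow(grid))
  for (nm in rev(priority)) {
    hit <- structures$masks[[nm]][lin]
    region[hit] <- nm
  }
  keep <- !is.na(region)
  out <- tibble(region = factor(region[keep], levels = priority),
                x = grid$x[keep], y = grid$y[keep], z = grid$z[keep])
  attr(out, "resolution") <- resolution
  attr(out, "regions") <- priority
  out
}
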