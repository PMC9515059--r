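#' Extract the accessible skin surface
#'
#' Finds body-surface voxels (gray crossing the body threshold from the
#' outside), keeps the accessible zone for transducer placement — by
#' default anterior, lateral and perineal/inferior directions, excluding
#' the posterior (table) side — and thins the points to roughly `step` mm
#' spacing by grid binning.
#'
#' @param ct a [ct_volume].
#' @param step target point spacing, mm (default 5).
#' @param body_threshold gray value separating body from air (500).
#' @param accessible predicate `function(points, centroid)` returning a
#'   logical vector; the default keeps points whose outward direction has
#'   posterior component `<= 0.2`.
#' @return Tibble of skin points `x`, `y`, `z` (mm).
#' @export
extract_skin_surface <- function(ct, step = 5, body_threshold = 500,
                                 accessible = NULL) {
  outside <- .outside_air_cpp(ct$values, dim(ct$values), body_threshold)
  if (all(outside)) abort("no body surface found (all-air volume)")
  body <- !outside  # filled body: enclosed gas cavities count as interior
  d <- dim(body)
  # surface voxels: body with a 6-neighbour in the outside air
  surf <- array(FALSE, d)
  shift_out <- function(ax, by) {
    idx_from <- idx_to <- rep(list(quote(expr = )), 3)
    n <- d[ax]
    if (by == 1) { idx_to[[ax]] <- 2:n; idx_from[[ax]] <- 1:(n - 1) }
    else { idx_to[[ax]] <- 1:(n - 1); idx_from[[ax]] <- 2:n }
    out <- array(FALSE, d)
    do.call(`[<-`, c(list(out), idx_to,
                     list(do.call(`[`, c(list(outside), idx_from)))))
  }
  for (ax in 1:3) {
    for (by in c(-1, 1)) surf <- surf | (body & shift_out(ax, by))
  }
  pts <- mask_centers(surf, ct$spacing, ct$origin)
  if (nrow(pts) == 0) abort("no body surface found")
  ctr <- colMeans(mask_centers(body, ct$spacing, ct$origin))
  if (is.null(accessible)) {
    accessible <- function(points, centroid) {
      dir <- sweep(points, 2, centroid, `-`)
      dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-9)
      dir[, 2] <= 0.2
    }
  }
  pts <- pts[accessible(pts, ctr), , drop = FALSE]
  if (nrow(pts) == 0) abort("no accessible skin surface")
  bin <- floor(sweep(pts, 2, rep(step, 3), `/`))
  keep <- !duplicated(bin)
  as_tibble(as.data.frame(pts[keep, , drop = FALSE]))
}

#' Assess a single ultrasound viewport
#'
#' Traces gray values from a skin point toward the target centroid with
#' 1 mm nearest-voxel sampling and applies the acoustic-window rules:
#' infeasible when `max(gray) > 1300` (dense tissue in the path), when
#' `min(gray) < 400` (gas; the first 2 mm at the skin are excluded from
#' this test so the air/skin partial-volume boundary does not trigger it),
#' or when the tissue depth to the centroid exceeds 120 mm. When several
#' rules fail the reported reason has priority dense > gas > depth.
#'
#' @param ct a [ct_volume].
#' @param skin_point numeric(3), mm (on the body surface).
#' @param target_centroid numeric(3), mm (inside the body).
#' @param max_gray_limit,min_gray_limit,max_depth thresholds.
#' @param skin_margin mm excluded from the min-gray test at the skin end.
#' @return One-row tibble: `x y z max_gray min_gray depth_mm feasible reason`.
#' @export
assess_viewport <- function(ct, skin_point, target_centroid,
                            max_gray_limit = 1300, min_gray_limit = 400,
                            max_depth = 120, skin_margin = 2) {
  st <- .viewport_stats_cpp(ct$values, dim(ct$values), ct$spacing, ct$origin,
                            matrix(as.numeric(skin_point), 1),
                            as.numeric(target_centroid),
                            1, skin_margin)
  classify_viewports(tibble(x = skin_point[1], y = skin_point[2],
                            z = skin_point[3]),
                     st, max_gray_limit, min_gray_limit, max_depth)
}

classify_viewports <- function(pts, st, max_gray_limit, min_gray_limit,
                               max_depth) {
  dense <- st[, 1] > max_gray_limit
  gas <- st[, 2] < min_gray_limit
  deep <- st[, 3] > max_depth
  reason <- rep("none", nrow(st))
  reason[deep] <- "depth"
  reason[gas] <- "gas"
  reason[dense] <- "dense"  # priority dense > gas > depth
  tibble(x = pts$x, y = pts$y, z = pts$z,
         max_gray = st[, 1], min_gray = st[, 2], depth_mm = st[, 3],
         feasible = !(dense | gas | deep),
         reason = factor(reason, levels = c("dense", "gas", "depth", "none")))
}

#' Map feasible viewports over the skin surface
#'
#' Applies [assess_viewport()] to every accessible skin point, with the
#' target centroid taken from the planning grid's PTV voxels.
#'
#' @param ct a [ct_volume].
#' @param grid planning grid from [voxelize()] (for the PTV centroid), or a
#'   numeric(3) centroid.
#' @param step skin discretization, mm.
#' @inheritParams assess_viewport
#' @return A `viewport_map` tibble (one row per skin point) with the
#'   centroid attached as attribute `centroid`.
#' @export
viewport_map <- function(ct, grid, step = 5, max_gray_limit = 1300,
                         min_gray_limit = 400, max_depth = 120,
                         skin_margin = 2) {
  centroid <- if (is.numeric(grid) && length(grid) == 3) {
    as.numeric(grid)
  } else {
    ptv <- grid[grid$region == "PTV", ]
    if (nrow(ptv) == 0) abort("planning grid has no PTV voxels")
    c(mean(ptv$x), mean(ptv$y), mean(ptv$z))
  }
  pts <- extract_skin_surface(ct, step = step)
  st <- .viewport_stats_cpp(ct$values, dim(ct$values), ct$spacing, ct$origin,
                            as.matrix(pts), centroid, 1, skin_margin)
  out <- classify_viewports(pts, st, max_gray_limit, min_gray_limit, max_depth)
  if (!any(out$feasible)) {
    abort(paste0("no feasible viewport on this phantom; revise the phantom ",
                 "spec (target too deep or acoustically shadowed)"))
  }
  attr(out, "centroid") <- centroid
  class(out) <- unique(c("viewport_map", class(out)))
  out
}

#' Write a viewport map as CSV
#' @param map a `viewport_map`.
#' @param path output path.
#' @export
write_viewport_map <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
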