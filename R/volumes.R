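#' CT-like gray-value volume
#'
#' A 3-D scalar grid on the offset-1000 scanner gray scale (air ≈ 0,
#' water ≈ 1000, i.e. gray = HU + 1000), with voxel spacing and origin in mm.
#' The centre of voxel `(i, j, k)` (1-based) lies at
#' `origin + (c(i, j, k) - 1) * spacing`. Coordinates are a right-handed
#' patient system: x to the patient's left, y posterior, z superior.
#'
#' @param values 3-D numeric array of gray values.
#' @param spacing numeric(3), voxel spacing in mm (all > 0).
#' @param origin numeric(3), position of the first voxel centre in mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(values)) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(spacing <= 0)) abort("spacing must be positive")
  if (!all(is.finite(values))) abort("volume values must be finite")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = "/"),
      " mm, gray range [", round(min(x$values)), ", ",
      round(max(x$values)), "]\n", sep = "")
  invisible(x)
}

#' Structure set (organ masks) on a CT lattice
#'
#' Named logical masks on the same lattice as a [ct_volume]. Recognised
#' labels are `PTV`, `BLADDER`, `RECTUM`, `BODY`, `SHELL3`, `SHELL9`
#' (further labels are carried along untouched).
#'
#' @param masks named list of logical 3-D arrays, identical dimensions.
#' @param spacing,origin lattice geometry in mm, as in [ct_volume].
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.list(masks), length(masks) > 0, !is.null(names(masks)))
  d <- dim(masks[[1]])
  for (m in masks) stopifnot(identical(dim(m), d), is.logical(m))
  structure(list(masks = masks, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  n <- vapply(x$masks, sum, 0)
  cat("<structure_set> ", paste(dim(x$masks[[1]]), collapse = " x "),
      " lattice\n", sep = "")
  for (i in seq_along(n)) {
    cat(sprintf("  %-8s %d voxels (%.1f cm^3)\n", names(n)[i], n[i],
                n[i] * prod(x$spacing) / 1000))
  }
  invisible(x)
}

# voxel-centre coordinates (mm) of TRUE entries of a mask
mask_centers <- function(mask, spacing, origin) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  sweep(sweep(idx - 1, 2, spacing, `*`), 2, origin, `+`) |>
    `colnames<-`(c("x", "y", "z"))
}

# centroid (mm) of a mask
mask_centroid <- function(mask, spacing, origin) {
  colMeans(mask_centers(mask, spacing, origin))
}

#' Read/write volumes as NIfTI
#'
#' `write_ct_volume()` stores a [ct_volume] (or a label volume built from a
#' [structure_set]) as NIfTI with mm voxel dimensions; `read_ct_volume()`
#' reads it back. Structure sets are encoded as integer label volumes
#' (0 background, then one code per mask in `labels` order).
#'
#' @param x a `ct_volume`.
#' @param path file path (`.nii` / `.nii.gz`).
#' @return `read_ct_volume()` returns a `ct_volume`.
#' @export
write_ct_volume <- function(x, path) {
  img <- RNifti::asNifti(x$values)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_ct_volume
#' @param origin origin (mm) to attach on read (NIfTI offset handling is
#'   deliberately kept out of scope; the phantom writer records the origin
#'   in a JSON sidecar).
#' @export
read_ct_volume <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim = dim(img)),
            spacing = RNifti::pixdim(img)[1:3], origin = origin)
}

#' @rdname write_ct_volume
#' @param structures a `structure_set`.
#' @param labels mask names to encode, in label order.
#' @export
write_structure_labels <- function(structures, path,
                                   labels = names(structures$masks)) {
  lab <- array(0L, dim = dim(structures$masks[[1]]))
  for (i in seq_along(labels)) {
    lab[structures$masks[[labels[i]]]] <- i
  }
  img <- RNifti::asNifti(lab)
  RNifti::pixdim(img) <- structures$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_ct_volume
#' @export
read_structure_labels <- function(path, labels, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(img), dim = dim(img))
  masks <- lapply(seq_along(labels), function(i) arr == i)
  names(masks) <- labels
  structure_set(masks, spacing = RNifti::pixdim(img)[1:3], origin = origin)
}
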