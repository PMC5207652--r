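# Image volumes, binary masks and the small amount of per-slice
# mathematical morphology the segmentation pipeline needs.

#' Construct an image volume
#'
#' A minimal container for a 3D scalar grid of CT attenuation values in
#' Hounsfield units (HU), with anisotropic physical voxel spacing.  The
#' third array index runs along the cranio-caudal axis and increases
#' cranially; the physical z position of slice `k` (1-based) is
#' `z_origin + (k - 1) * spacing[3]`.
#'
#' @param values 3D numeric array of HU values (a 2D matrix is promoted to
#'   a single-slice volume).
#' @param spacing numeric length-3, voxel spacing in mm per axis (dx, dy, dz);
#'   all components must be positive.
#' @param z_origin physical z position (mm) of the first slice.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing, z_origin = 0) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (any(dim(values) < 1L)) stop("`values` must be non-empty")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm)")
  structure(
    list(values = values, spacing = spacing, z_origin = as.numeric(z_origin)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU range [%g, %g]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Physical z positions of all slices of a volume
#' @param volume an [image_volume].
#' @return numeric vector of slice z positions in mm (index increases cranially).
#' @export
slice_positions <- function(volume) {
  volume$z_origin + (seq_len(dim(volume$values)[3]) - 1) * volume$spacing[3]
}

# Masks are plain logical arrays on the parent volume's grid.  These
# helpers centralize the grid-compatibility checks every operation needs.
as_mask <- function(x) {
  if (is.null(dim(x))) stop("mask must be an array")
  storage.mode(x) <- "logical"
  x
}

check_same_grid <- function(a, b, what = "masks") {
  da <- if (inherits(a, "image_volume")) dim(a$values) else dim(a)
  db <- if (inherits(b, "image_volume")) dim(b$values) else dim(b)
  if (!identical(as.integer(da), as.integer(db)))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(TRUE)
}

# ---- per-slice morphology -------------------------------------------------
# All structuring elements are 2D discs applied slice by slice (the axial
# in-plane resolution is much finer than the slice spacing on thoracic CT,
# so in-plane morphology is the natural choice).

disc_offsets <- function(radius) {
  if (radius < 0) stop("radius must be >= 0")
  r <- as.integer(ceiling(radius))
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= radius^2 + 1e-9, , drop = FALSE]
  off
}

# Shift a 3D logical array in-plane by (dx, dy), padding with `fill`.
shift_xy <- function(a, dx, dy, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  if (length(xs) < 1 || length(ys) < 1) return(out)
  out[xs, ys, ] <- a[xs - dx, ys - dy, , drop = FALSE]
  out
}

#' Per-slice binary dilation with a disc structuring element
#' @param mask logical 3D array.
#' @param radius disc radius in voxels.
#' @return dilated logical array of the same shape.
#' @export
dilate_mask <- function(mask, radius = 1) {
  mask <- as_mask(mask)
  if (radius <= 0) return(mask)
  off <- disc_offsets(radius)
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(off)))
    out <- out | shift_xy(mask, off$dx[i], off$dy[i], fill = FALSE)
  out
}

#' Per-slice binary erosion with a disc structuring element
#' @inheritParams dilate_mask
#' @return eroded logical array of the same shape.
#' @export
erode_mask <- function(mask, radius = 1) {
  mask <- as_mask(mask)
  if (radius <= 0) return(mask)
  off <- disc_offsets(radius)
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(off)))
    out <- out & shift_xy(mask, off$dx[i], off$dy[i], fill = FALSE)
  out
}

#' Per-slice morphological opening (erosion then dilation)
#' @inheritParams dilate_mask
#' @export
open_mask <- function(mask, radius = 1) {
  if (radius <= 0) return(as_mask(mask))
  dilate_mask(erode_mask(mask, radius), radius)
}

#' Per-slice morphological closing (dilation then erosion)
#' @inheritParams dilate_mask
#' @export
close_mask <- function(mask, radius = 1) {
  if (radius <= 0) return(as_mask(mask))
  erode_mask(dilate_mask(mask, radius), radius)
}

# Geodesic reconstruction of `seed` inside `region` under per-slice
# 4-connectivity: repeatedly dilate the seed with a cross element, clipped
# to the region, until a fixed point.  Used for border-connected background
# detection (cavity filling) and hole filling.
reconstruct_2d <- function(seed, region) {
  seed <- as_mask(seed) & region
  cross <- data.frame(dx = c(0, 1, -1, 0, 0), dy = c(0, 0, 0, 1, -1))
  repeat {
    grown <- array(FALSE, dim(seed))
    for (i in seq_len(nrow(cross)))
      grown <- grown | shift_xy(seed, cross$dx[i], cross$dy[i], fill = FALSE)
    grown <- grown & region
    if (identical(grown, seed)) return(seed)
    seed <- grown
  }
}

# Fill, per axial slice, every hole (FALSE region not 4-connected to the
# lateral slice border) of `mask`.
fill_holes_2d <- function(mask) {
  mask <- as_mask(mask)
  d <- dim(mask)
  bg <- !mask
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  outside <- reconstruct_2d(border & bg, bg)
  mask | (bg & !outside)
}
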