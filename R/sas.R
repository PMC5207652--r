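# Standardized anatomic space (SAS): vertebral-landmark calibration and
# the piecewise-linear cranio-caudal mapping between subject space and the
# standardized axis, plus the proportional linear-mapping baseline.

default_landmark_labels <- function() paste0("T", 2:10)

#' Construct a vertebral landmark set
#'
#' Ordered vertebral mid-level landmarks with their physical z positions.
#' The default labels are the mid-axial levels of T2 through T10.  The z
#' positions must be strictly monotone along the label order; with the
#' package's cranial-up z convention, T2..T10 run caudally so z typically
#' decreases along the list.
#'
#' @param labels character vector of unique landmark names, cranial first.
#' @param z numeric vector of physical positions (mm), one per label,
#'   strictly monotone.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(z, labels = default_landmark_labels()) {
  if (length(z) != length(labels)) stop("`z` and `labels` lengths differ")
  if (length(z) < 2) stop("at least 2 landmarks are required")
  if (anyDuplicated(labels)) stop("landmark labels must be unique")
  dz <- diff(z)
  if (any(dz == 0) || !(all(dz > 0) || all(dz < 0)))
    stop("landmark z positions must be strictly monotone")
  structure(list(labels = as.character(labels), z = as.numeric(z)),
            class = "landmark_set")
}

#' Calibrate a standardized anatomic space model
#'
#' Each reference subject's landmark positions are affinely normalized so
#' the first landmark maps to 0 and the last to 1 (removing per-subject
#' height and table position while preserving relative spacing); the mean
#' standardized location `M_i` of each landmark is the per-landmark
#' arithmetic mean of the normalized positions across references.
#'
#' @param reference_landmarks list of [landmark_set] objects with identical
#'   labels.
#' @return object of class `sas_model` with fields `labels`, `M`
#'   (monotone increasing, `M[1] = 0`, `M[n] = 1`) and `n_refs`.
#' @export
sas_calibrate <- function(reference_landmarks) {
  if (length(reference_landmarks) < 1) stop("at least one reference set is required")
  labels <- reference_landmarks[[1]]$labels
  norm <- vapply(reference_landmarks, function(lm) {
    if (!inherits(lm, "landmark_set")) stop("references must be landmark_set objects")
    if (!identical(lm$labels, labels))
      stop("landmark labels differ across reference sets")
    (lm$z - lm$z[1]) / (lm$z[length(lm$z)] - lm$z[1])
  }, numeric(length(labels)))
  M <- rowMeans(norm)
  structure(list(labels = labels, M = M, n_refs = length(reference_landmarks)),
            class = "sas_model")
}

#' @export
print.sas_model <- function(x, ...) {
  cat(sprintf("<sas_model> %d landmarks (%s..%s), calibrated on %d reference set(s)\n",
              length(x$labels), x$labels[1], x$labels[length(x$labels)], x$n_refs))
  print(round(stats::setNames(x$M, x$labels), 4))
  invisible(x)
}

# Normalize a subject's landmark z to the model's 0..1 direction (0 at the
# first label regardless of whether subject z increases or decreases).
subject_axis <- function(subject) {
  z <- subject$z
  (z - z[1]) / (z[length(z)] - z[1])
}

#' Map a physical z position to the standardized coordinate
#'
#' Piecewise-linear interpolation between the subject's landmarks `L_i`
#' and the calibrated mean locations `M_i`; positions beyond the first or
#' last landmark are extrapolated with the slope of the adjacent segment.
#'
#' @param subject a [landmark_set] for the subject.
#' @param model a calibrated `sas_model` with the same labels.
#' @param z physical position(s) in mm.
#' @return standardized coordinate(s) `s` (0 at the first landmark, 1 at
#'   the last).
#' @export
to_sas <- function(subject, model, z) {
  if (!identical(subject$labels, model$labels))
    stop("subject and model landmark labels differ")
  u <- subject_axis(subject)             # subject landmarks on a 0..1 axis
  if (any(diff(u) <= 0)) stop("degenerate landmark segment in subject")
  zs <- subject$z
  span <- zs[length(zs)] - zs[1]
  uz <- (z - zs[1]) / span               # direction-normalized query
  piecewise_interp(u, model$M, uz)
}

# Piecewise-linear interpolation on strictly increasing nodes x -> y with
# end-segment linear extrapolation.
piecewise_interp <- function(x, y, xq) {
  n <- length(x)
  i <- findInterval(xq, x, all.inside = TRUE)  # segment index in 1..n-1
  y[i] + (xq - x[i]) / (x[i + 1] - x[i]) * (y[i + 1] - y[i])
}

#' Map a standardized coordinate back to an acquired slice
#'
#' Inverts the piecewise-linear mapping to a physical z position and
#' returns the nearest acquired slice; acquired slices are never
#' resampled.  An exact tie between two slices resolves to the more
#' cranial (larger z) slice.
#'
#' @param subject a [landmark_set].
#' @param model a calibrated `sas_model`.
#' @param s standardized coordinate(s).
#' @param slice_grid physical z positions (mm) of the acquired slices,
#'   strictly monotone.
#' @param subject_id identifier used in out-of-range error messages.
#' @return integer slice index/indices into `slice_grid` (1-based).
#' @export
from_sas <- function(subject, model, s, slice_grid, subject_id = "subject") {
  z <- sas_invert(subject, model, s)
  dzg <- diff(slice_grid)
  if (any(dzg == 0) || !(all(dzg > 0) || all(dzg < 0)))
    stop("slice grid must be strictly monotone")
  lo <- min(slice_grid); hi <- max(slice_grid)
  half <- min(abs(dzg)) / 2
  if (any(z < lo - half | z > hi + half))
    stop(sprintf("standardized coordinate maps outside the acquired stack for %s",
                 subject_id))
  vapply(z, function(zi) {
    d <- abs(slice_grid - zi)
    cand <- which(d <= min(d) + 1e-9)
    cand[which.max(slice_grid[cand])]   # tie -> more cranial slice
  }, integer(1))
}

#' Invert the standardized mapping to physical z
#'
#' @inheritParams from_sas
#' @return physical z position(s) in mm.
#' @export
sas_invert <- function(subject, model, s) {
  if (!identical(subject$labels, model$labels))
    stop("subject and model landmark labels differ")
  u <- subject_axis(subject)
  if (any(diff(u) <= 0)) stop("degenerate landmark segment in subject")
  uq <- piecewise_interp(model$M, u, s)
  zs <- subject$z
  zs[1] + uq * (zs[length(zs)] - zs[1])
}

#' Proportional linear-mapping baseline
#'
#' The naive alternative to SAS: a standardized fraction is interpreted
#' proportionally between the first and last slices of the (trimmed)
#' thoracic volume, ignoring the subject's landmark configuration.
#'
#' @param slice_grid physical z positions (mm) of the acquired slices.
#' @param s_fraction fraction(s) in `[0, 1]`; 0 is the first (most caudal)
#'   slice, 1 the last.
#' @return integer slice index/indices (1-based).
#' @export
linear_baseline <- function(slice_grid, s_fraction) {
  n <- length(slice_grid)
  if (n < 2 || abs(slice_grid[n] - slice_grid[1]) == 0)
    stop("slice grid has zero span")
  idx <- 1 + s_fraction * (n - 1)
  out <- as.integer(floor(idx + 0.5))    # ties round up = more cranial
  pmin(pmax(out, 1L), n)
}

#' Half-level standardized sampling grid
#'
#' The standardized positions used for per-level reporting: every
#' landmark mid-level plus the midpoint between consecutive landmarks
#' (e.g. T2, T2-T3, T3, ..., T10: 17 positions for 9 landmarks).
#'
#' @param model a calibrated `sas_model`.
#' @return data.frame with columns `label` and `s`.
#' @export
sas_half_level_grid <- function(model) {
  n <- length(model$M)
  s <- numeric(2 * n - 1)
  lab <- character(2 * n - 1)
  s[seq(1, 2 * n - 1, by = 2)] <- model$M
  lab[seq(1, 2 * n - 1, by = 2)] <- model$labels
  if (n > 1) {
    mid <- (model$M[-n] + model$M[-1]) / 2
    s[seq(2, 2 * n - 2, by = 2)] <- mid
    lab[seq(2, 2 * n - 2, by = 2)] <-
      paste(model$labels[-n], model$labels[-1], sep = "-")
  }
  data.frame(label = lab, s = s, stringsAsFactors = FALSE)
}

#' Label a standardized coordinate at half-level granularity
#'
#' Returns the nearest half-level label (mid-vertebra, e.g. `"T8"`, or
#' between vertebrae, e.g. `"T6-T7"`).  Coordinates beyond the landmark
#' span are labeled with the end label plus a `-sup`/`-inf` suffix.
#'
#' @param s standardized coordinate(s).
#' @param model a calibrated `sas_model`.
#' @return character label(s).
#' @export
sas_label <- function(s, model) {
  grid <- sas_half_level_grid(model)
  n <- nrow(grid)
  gap1 <- (grid$s[2] - grid$s[1]) / 2
  gapn <- (grid$s[n] - grid$s[n - 1]) / 2
  vapply(s, function(si) {
    if (si < grid$s[1] - gap1) return(paste0(grid$label[1], "-sup"))
    if (si > grid$s[n] + gapn) return(paste0(grid$label[n], "-inf"))
    grid$label[which.min(abs(grid$s - si))]
  }, character(1))
}
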