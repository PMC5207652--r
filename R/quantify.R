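# Normalized fat quantity and attenuation-quality measures: skeletal
# bounding-box normalizing length, volume/area measurement records, and
# attenuation-histogram summary parameters.

#' Skeletal bounding-box normalizing length
#'
#' The Euclidean diagonal L (mm) of the tight axis-aligned physical
#' bounding box of the thoracic skeleton mask.  Fat volumes are
#' normalized by L^3 and areas by L^2, making the measures dimensionless
#' and invariant to isotropic body-size rescaling.  The physical extent
#' along each axis counts whole voxels, so a single voxel of spacing
#' (1, 1, 5) mm has L = sqrt(1 + 1 + 25).
#'
#' @param bone_mask logical skeletal mask.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @return normalizing length L in mm.
#' @export
skeletal_diagonal <- function(bone_mask, spacing) {
  idx <- which(as_mask(bone_mask), arr.ind = TRUE)
  if (nrow(idx) == 0) stop("bone mask is empty; cannot compute normalizing length")
  extent <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) * spacing
  sqrt(sum(extent^2))
}

#' Attenuation histogram summary
#'
#' Five location parameters of an attenuation (HU) sample: mean `H_m`,
#' median `H_md`, mode `H_p`, and the lower and upper quartiles `H_lq`,
#' `H_uq`.  Quartiles use linear interpolation between order statistics
#' (R quantile type 7).  The mode is the center of the fullest
#' `bin_width`-HU-wide bin on an integer-centered grid spanning the fat
#' window (extended to the data range when values fall outside it);
#' ties resolve to the most negative bin.
#'
#' @param hu_values numeric vector of HU values (length >= 1).
#' @param window a [fat_window] anchoring the mode-binning grid.
#' @param bin_width mode bin width in HU (default 1; CT attenuation values
#'   are near-integer).
#' @return object of class `histogram_summary`: list with `H_m`, `H_md`,
#'   `H_p`, `H_lq`, `H_uq`, `n_voxels`.
#' @export
histogram_summary <- function(hu_values, window = fat_window(), bin_width = 1) {
  hu_values <- hu_values[is.finite(hu_values)]
  if (length(hu_values) < 1) stop("histogram summary of an empty sample")
  q <- stats::quantile(hu_values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  lo <- min(floor(window$lower), floor(min(hu_values)))
  hi <- max(ceiling(window$upper), ceiling(max(hu_values)))
  centers <- seq(lo, hi, by = bin_width)
  bin <- pmin(pmax(round((hu_values - lo) / bin_width), 0), length(centers) - 1)
  counts <- tabulate(bin + 1L, nbins = length(centers))
  mode_hu <- centers[which.max(counts)]   # which.max -> first = most negative
  structure(list(H_m = mean(hu_values), H_md = q[2], H_p = mode_hu,
                 H_lq = q[1], H_uq = q[3], n_voxels = length(hu_values)),
            class = "histogram_summary")
}

#' @export
print.histogram_summary <- function(x, ...) {
  cat(sprintf("<histogram_summary> n=%d  H_m=%.1f  H_md=%.1f  H_p=%.1f  H_lq=%.1f  H_uq=%.1f (HU)\n",
              x$n_voxels, x$H_m, x$H_md, x$H_p, x$H_lq, x$H_uq))
  invisible(x)
}

#' Measure a fat compartment
#'
#' Computes the raw measure (volume in mm^3 for `scope = "volume"`, area
#' in mm^2 for a slice scope), the skeleton-normalized measure (raw / L^3
#' or raw / L^2), and the attenuation histogram summary of the HU values
#' under the mask.  An empty mask yields a zero measure and `NULL`
#' histogram rather than an error.
#'
#' @param mask logical compartment mask (3D; for a slice measurement pass
#'   the slice index).
#' @param volume parent [image_volume].
#' @param L normalizing length (mm) from [skeletal_diagonal].
#' @param scope `"volume"` or `"slice"`.
#' @param slice 1-based slice index, required when `scope = "slice"`.
#' @param subject_id,compartment,region metadata carried into the record.
#' @return object of class `measurement_record`.
#' @export
measure_compartment <- function(mask, volume, L, scope = c("volume", "slice"),
                                slice = NULL, subject_id = NA_character_,
                                compartment = NA_character_,
                                region = "chest") {
  scope <- match.arg(scope)
  check_same_grid(volume, mask, "volume and compartment mask")
  if (!is.finite(L) || L <= 0) stop("normalizing length L must be positive")
  sp <- volume$spacing
  if (scope == "slice") {
    if (is.null(slice)) stop("`slice` index required for slice scope")
    m <- mask[, , slice, drop = FALSE]
    vals <- volume$values[, , slice, drop = FALSE][m]
    raw <- sum(m) * sp[1] * sp[2]
    normalized <- raw / L^2
    scope_label <- paste0("slice@", slice)
  } else {
    m <- mask
    vals <- volume$values[m]
    raw <- sum(m) * prod(sp)
    normalized <- raw / L^3
    scope_label <- "volume"
  }
  hist_sum <- if (length(vals) > 0) histogram_summary(vals) else NULL
  if (length(vals) == 0)
    message(sprintf("empty mask for %s/%s (%s): zero measure recorded",
                    subject_id, compartment, scope_label))
  structure(list(subject_id = subject_id, compartment = compartment,
                 region = region, scope = scope_label,
                 raw = raw, normalized = normalized, L = L,
                 histogram = hist_sum),
            class = "measurement_record")
}

#' Closed-form truncated-normal moments
#'
#' Mean and quantiles of a normal distribution with parameters `mean`,
#' `sd` truncated to `[lower, upper]`.  Serves as the analytic oracle for
#' histogram-parameter recovery on synthetic fat compartments.
#'
#' @param mean,sd parent normal parameters.
#' @param lower,upper truncation bounds.
#' @return list with `mean`, and function `quantile(p)`.
#' @export
truncnorm_moments <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  tmean <- mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / Z
  qfun <- function(p)
    mean + sd * stats::qnorm(stats::pnorm(a) + p * Z)
  list(mean = tmean, quantile = qfun)
}

# Inverse-CDF sampler for the same truncated normal; the generator uses it
# so every synthetic fat voxel lies inside the window by construction.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mean, sd)
}
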