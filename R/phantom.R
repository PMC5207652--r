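# Seeded synthetic thoracic CT phantom cohorts with complete ground
# truth.  The phantom is deliberately simple geometry -- an elliptical
# body cylinder, posterior lung ellipsoids, an inset rib-cage interface
# capped inferiorly by a hemispherical diaphragm dome, a cortical bone
# annulus carrying marrow pseudo-fat, a subcutaneous fat ring and an
# anterior mediastinal VAT blob -- chosen as the simplest configuration
# that exercises every segmentation rule (cavity filling, interface
# split, sub-diaphragm exclusion, marrow correction).  Fat HU values are
# drawn from truncated normals restricted to the fat window so analytic
# truncated-normal moments serve as oracles downstream.

#' Phantom cohort parameters
#'
#' All knobs of the synthetic cohort generator.  `coupling_level` gives,
#' per compartment, the standardized coordinate (0 at the first landmark,
#' 1 at the last) at which the slice fat area is planted to be
#' proportional to the compartment's total volume across subjects (with
#' relative noise `coupling_noise`); areas at other levels carry
#' independent per-landmark variability of relative SD `area_noise`.
#' Group "B" subjects have their VAT attenuation mean shifted by
#' `group_hu_shift` HU.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param grid_shape voxel grid (nx, ny, nz).
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @param landmark_labels ordered vertebral landmark names, cranial first.
#' @param landmark_jitter per-gap multiplicative jitter SD (fraction of the
#'   inter-landmark gap).
#' @param warp_strength magnitude of the per-subject monotone cubic warp of
#'   landmark spacing (0 = equally spaced; keep < 0.4 for guaranteed
#'   monotonicity).
#' @param sat_hu_mean,sat_hu_sd SAT attenuation parameters (HU) before
#'   truncation to the fat window.
#' @param vat_hu_mean,vat_hu_sd VAT attenuation parameters (HU).
#' @param soft_tissue_hu_mean,soft_tissue_hu_sd non-fat soft tissue HU.
#' @param subject_hu_sd SD (HU) of the per-subject offset added to each
#'   compartment's attenuation mean, giving subjects correlated volume-
#'   and slice-level histogram parameters as in real cohorts.
#' @param bone_hu,lung_hu cortical bone and lung parenchyma HU.
#' @param marrow_fat_fraction fraction of skeletal-annulus voxels assigned
#'   fat-window HU (marrow pseudo-fat, excluded from the bone mask).
#' @param coupling_level named numeric (`SAT`, `VAT`): standardized
#'   coordinates of the planted best-slice levels.
#' @param coupling_noise relative SD of the planted area-volume coupling.
#' @param area_noise relative SD of per-landmark area variability away from
#'   the coupled level.
#' @param group_hu_shift HU offset added to group-B VAT attenuation means.
#' @param window a [fat_window].
#' @param seed integer RNG seed; all randomness derives from it.
#' @return validated list of class `phantom_params`.
#' @export
phantom_params <- function(n_subjects = 40,
                           grid_shape = c(64, 64, 40),
                           spacing = c(4.5, 4.5, 5),
                           landmark_labels = default_landmark_labels(),
                           landmark_jitter = 0.05,
                           warp_strength = 0.3,
                           sat_hu_mean = -100, sat_hu_sd = 20,
                           vat_hu_mean = -70, vat_hu_sd = 8,
                           soft_tissue_hu_mean = 40, soft_tissue_hu_sd = 10,
                           subject_hu_sd = 5,
                           bone_hu = 700, lung_hu = -800,
                           marrow_fat_fraction = 0.02,
                           coupling_level = c(SAT = 0.75, VAT = 0.625),
                           coupling_noise = 0.02,
                           area_noise = 0.15,
                           group_hu_shift = -7,
                           window = fat_window(),
                           seed = 1) {
  p <- as.list(environment())
  check_field <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid phantom parameter `%s`: %s", field, msg))
  }
  check_field(is.numeric(p$n_subjects) && p$n_subjects >= 2, "n_subjects", ">= 2 required")
  check_field(length(p$grid_shape) == 3 && all(p$grid_shape >= 8), "grid_shape",
              "three dims >= 8 required")
  check_field(length(p$spacing) == 3 && all(p$spacing > 0), "spacing",
              "three positive spacings required")
  check_field(length(p$landmark_labels) >= 2 && !anyDuplicated(p$landmark_labels),
              "landmark_labels", "at least 2 unique labels")
  check_field(p$landmark_jitter >= 0, "landmark_jitter", "must be >= 0")
  check_field(p$warp_strength >= 0 && p$warp_strength < 0.45, "warp_strength",
              "must be in [0, 0.45) for monotone warps")
  for (f in c("sat_hu_sd", "vat_hu_sd", "soft_tissue_hu_sd", "subject_hu_sd",
              "coupling_noise", "area_noise"))
    check_field(p[[f]] >= 0, f, "must be >= 0")
  check_field(all(c("SAT", "VAT") %in% names(p$coupling_level)),
              "coupling_level", "needs named SAT and VAT entries")
  check_field(all(p$coupling_level >= 0 & p$coupling_level <= 1),
              "coupling_level", "must lie within the landmark span [0, 1]")
  check_field(p$marrow_fat_fraction >= 0 && p$marrow_fat_fraction <= 0.5,
              "marrow_fat_fraction", "must be in [0, 0.5]")
  check_field(is.numeric(p$seed) && length(p$seed) == 1 && is.finite(p$seed),
              "seed", "a single finite integer seed is required")
  p$n_subjects <- as.integer(p$n_subjects)
  p$grid_shape <- as.integer(p$grid_shape)
  class(p) <- "phantom_params"
  p
}

# Area-to-volume coupling constants (mm^-1), cohort-invariant by design:
# roughly 1 / (effective cranio-caudal extent) of each compartment so the
# planted coupled-slice area is commensurate with its neighbors.
COUPLING_C <- c(SAT = 1 / 150, VAT = 1 / 80)

# Per-subject monotone warp of the unit landmark axis: identity plus a
# quadratic + cubic perturbation vanishing at both ends.
warp_fun <- function(strength, a1, a2) {
  function(u) u + strength * (a1 * u * (1 - u) + a2 * u * (1 - u) * (1 - 2 * u))
}

# Nominal standardized node positions (equally spaced labels).
nominal_nodes <- function(n_labels) seq(0, 1, length.out = n_labels)

#' Planted best-slice labels of a parameter set
#'
#' Returns, per compartment, the half-level label nearest the configured
#' `coupling_level` on the nominal (equally spaced) standardized grid.
#'
#' @param params a [phantom_params].
#' @return named character vector (`SAT`, `VAT`).
#' @export
planted_labels <- function(params) {
  n <- length(params$landmark_labels)
  model <- structure(list(labels = params$landmark_labels,
                          M = nominal_nodes(n), n_refs = 0),
                     class = "sas_model")
  c(SAT = sas_label(params$coupling_level[["SAT"]], model),
    VAT = sas_label(params$coupling_level[["VAT"]], model))
}

# Draw one subject's landmark set.  T2 sits near the lung apex and the
# span covers most of the lung extent; gaps get multiplicative jitter.
draw_landmarks <- function(params, za, zb) {
  n <- length(params$landmark_labels)
  w <- warp_fun(params$warp_strength, stats::runif(1, -1, 1), stats::runif(1, -1, 1))
  z_t2 <- za - stats::runif(1, 2, 10)
  # wide span variability: the inferior landmark's position within the
  # stack varies by several vertebral levels across subjects
  span <- (za - zb) * min(max(stats::rnorm(1, 0.80, 0.10), 0.60), 0.93)
  u <- w(nominal_nodes(n))
  gaps <- diff(u) * span
  jit <- pmax(0.1, 1 + params$landmark_jitter * stats::rnorm(n - 1))
  gaps <- gaps * jit
  gaps <- gaps / sum(gaps) * span
  z <- z_t2 - c(0, cumsum(gaps))        # decreasing: T2 cranial, T10 caudal
  landmark_set(z, params$landmark_labels)
}

# True standardized coordinate of physical z under a subject's landmarks
# and the nominal node grid (the generator's own mapping truth).
true_s_of_z <- function(landmarks, z) {
  zs <- landmarks$z
  u_nodes <- (zs - zs[1]) / (zs[length(zs)] - zs[1])
  uq <- (z - zs[1]) / (zs[length(zs)] - zs[1])
  piecewise_interp(u_nodes, nominal_nodes(length(zs)), uq)
}

true_z_of_s <- function(landmarks, s) {
  zs <- landmarks$z
  u_nodes <- (zs - zs[1]) / (zs[length(zs)] - zs[1])
  uq <- piecewise_interp(nominal_nodes(length(zs)), u_nodes, s)
  zs[1] + uq * (zs[length(zs)] - zs[1])
}

# Piecewise-linear per-landmark noise field over the standardized axis,
# clamped to the end values outside [0, 1].
noise_field <- function(node_noise) {
  nodes <- nominal_nodes(length(node_noise))
  function(s) piecewise_interp(nodes, node_noise, pmin(pmax(s, 0), 1))
}

#' Generate one synthetic subject
#'
#' Internal workhorse of [generate_cohort]; exported for fixture building.
#'
#' @param params a [phantom_params].
#' @param subject_id identifier string.
#' @param group group label ("A" or "B").
#' @param seed subject-level seed.
#' @return object of class `synthetic_subject`: `volume`, masks
#'   (`body_mask`, `lung_mask`, `bone_mask`, `interface_mask`),
#'   `landmarks`, and a `truth` list (masks, realized volumes/areas,
#'   per-level table, generative scales, group, BMI).
#' @export
generate_subject <- function(params, subject_id = "s01", group = "A", seed = 1) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  d <- params$grid_shape; sp <- params$spacing
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  xs <- (seq_len(nx) - (nx + 1) / 2) * sp[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * sp[2]
  zs <- (seq_len(nz) - 1) * sp[3]
  X <- matrix(xs, nx, ny); Y <- matrix(ys, nx, ny, byrow = TRUE)
  zmax <- zs[nz]

  # -- global geometry ------------------------------------------------------
  rx0 <- 105 * stats::rnorm(1, 1, 0.04); ry0 <- 85 * stats::rnorm(1, 1, 0.04)
  rx0 <- min(rx0, (nx / 2 - 1.5) * sp[1]); ry0 <- min(ry0, (ny / 2 - 1.5) * sp[2])
  zc <- zmax / 2
  za <- stats::runif(1, 0.84, 0.92) * zmax        # lung apex (cranial)
  zb <- stats::runif(1, 0.18, 0.26) * zmax        # lung base (caudal)
  z_edge <- zb - 8                                 # diaphragm rim
  dome_h <- stats::runif(1, 24, 32)                # dome height

  # -- pass 1: fixed geometry (body, cavity, bone, lungs) -------------------
  logical_stack <- function() array(FALSE, d)
  body <- logical_stack(); lung <- logical_stack(); bone <- logical_stack()
  iface <- logical_stack()
  rx_i0 <- 0.65 * rx0; ry_i0 <- 0.65 * ry0
  rr_dome <- (X / rx_i0)^2 + (Y / ry_i0)^2
  z_base <- z_edge + dome_h * pmax(0, 1 - rr_dome)
  barrel_of <- function(z) 1 - 0.10 * ((z - zc) / zc)^2
  for (k in seq_len(nz)) {
    z <- zs[k]
    barrel <- barrel_of(z)
    rx <- rx0 * barrel; ry <- ry0 * barrel
    E <- (X / rx)^2 + (Y / ry)^2
    body[, , k] <- E <= 1
    cav <- E <= 0.65^2 & z > z_base
    iface[, , k] <- cav
    bone[, , k] <- E > 0.66^2 & E <= 0.76^2
    lz <- ((z - (za + zb) / 2) / ((za - zb) / 2))^2
    if (lz < 1) {
      sc <- sqrt(1 - lz)
      lung2d <- FALSE
      for (sgn in c(-1, 1)) {
        lx <- sgn * 0.45 * rx_i0
        ly <- 0.45 * ry_i0
        lung2d <- lung2d | (((X - lx) / (0.42 * rx_i0 * sc))^2 +
                              ((Y - ly) / (0.45 * ry_i0 * sc))^2 <= 1)
      }
      lung[, , k] <- lung2d & cav
    }
  }
  # marrow pseudo-fat: a fraction of the skeletal-annulus *interior* (so
  # the closing-based correction provably covers it); excluded from the
  # cortical bone mask because it images as fat
  marrow <- logical_stack()
  if (params$marrow_fat_fraction > 0) {
    interior <- bone & erode_mask(bone, 1)
    cand <- which(interior)
    midx <- cand[stats::runif(length(cand)) < params$marrow_fat_fraction]
    marrow[midx] <- TRUE
    bone[midx] <- FALSE
  }

  # trimmed thoracic slice range from the realized lung mask (mirrors
  # trim_thoracic_region exactly)
  lung_slices <- which(apply(lung, 3, any))
  base_k <- lung_slices[1]; apex_k <- lung_slices[length(lung_slices)]
  lo <- max(1L, base_k - as.integer(ceiling(5 / sp[3])))
  hi <- min(nz, apex_k + as.integer(ceiling(15 / sp[3])))
  trim <- lo:hi
  za_real <- zs[apex_k]; zb_real <- zs[base_k]
  # landmarks anchored to the realized lung extent so every standardized
  # half-level maps inside the trimmed stack for every subject
  landmarks <- draw_landmarks(params, za_real, zb_real)
  gap_mm <- abs(landmarks$z[1] - landmarks$z[length(landmarks$z)]) /
    (length(landmarks$z) - 1)

  # -- per-compartment target area profiles --------------------------------
  s_of_z <- true_s_of_z(landmarks, zs)
  amp_s <- min(max(4800 * exp(stats::rnorm(1, 0, 0.25)), 2600), 6000)
  amp_v <- min(max(1500 * exp(stats::rnorm(1, 0, 0.35)), 600), 3100)
  eta_s <- noise_field(stats::rnorm(length(landmarks$z), 0, params$area_noise))
  eta_v <- noise_field(stats::rnorm(length(landmarks$z), 0, params$area_noise))
  shape_s <- function(s) 1 + 0.12 * cos(2 * pi * (pmin(pmax(s, -0.2), 1.2) - 0.5))
  zv_lo <- z_edge + dome_h + 5; zv_hi <- za
  shape_v <- function(z) ifelse(z > zv_lo & z < zv_hi,
                                sin(pi * (z - zv_lo) / (zv_hi - zv_lo)), 0)

  A_sat <- amp_s * shape_s(s_of_z) * pmax(0.2, 1 + eta_s(s_of_z))
  A_vat <- amp_v * shape_v(zs) * pmax(0.2, 1 + eta_v(s_of_z))

  # plant the area-to-volume coupling at the configured level, blending the
  # override linearly into the neighboring landmark gap so that small
  # downstream slice-selection offsets stay strongly coupled
  plant <- function(A, compartment) {
    s_star <- params$coupling_level[[compartment]]
    z_star <- true_z_of_s(landmarks, s_star)
    k_star <- which.min(abs(zs - z_star))
    wz <- pmax(0, 1 - abs(zs - zs[k_star]) / gap_mm)
    wz[k_star] <- 1
    eps <- stats::rnorm(1, 0, params$coupling_noise)
    cc <- COUPLING_C[[compartment]] * (1 + eps)
    a_star <- cc * sum(A[trim]) * sp[3]
    for (it in 1:6) {
      A_cur <- (1 - wz) * A + wz * a_star
      a_star <- cc * sum(A_cur[trim]) * sp[3]
    }
    list(A = (1 - wz) * A + wz * a_star, k_star = k_star, a_star = a_star)
  }
  ps <- plant(A_sat, "SAT"); pv <- plant(A_vat, "VAT")
  A_sat <- ps$A; A_vat <- pv$A

  # -- pass 2: fat compartments with the target area profiles ---------------
  sat <- logical_stack(); vat <- logical_stack()
  for (k in seq_len(nz)) {
    z <- zs[k]
    barrel <- barrel_of(z)
    rx <- rx0 * barrel; ry <- ry0 * barrel
    E <- (X / rx)^2 + (Y / ry)^2            # squared elliptic radius
    # SAT ring: inner scale from the target area
    a_k <- min(max(A_sat[k], 400), 0.3276 * pi * rx * ry)
    s_in <- sqrt(1 - a_k / (pi * rx * ry))
    sat[, , k] <- E <= 1 & E > s_in^2
    # anterior mediastinal VAT blob with target area
    av <- min(max(A_vat[k], 0), 3600)
    if (av > 4 * sp[1] * sp[2]) {
      b <- sqrt(av / (pi * 2.6)); a <- 2.6 * b
      yv <- -0.5 * ry_i0
      blob <- ((X / a)^2 + ((Y - yv) / b)^2) <= 1
      vat[, , k] <- blob & iface[, , k] & !lung[, , k]
    }
  }
  sat <- sat & !bone & !marrow

  # -- attenuation values ---------------------------------------------------
  w <- params$window
  hu <- array(-1000, d)
  nbody <- sum(body)
  hu[body] <- stats::rnorm(nbody, params$soft_tissue_hu_mean,
                           params$soft_tissue_hu_sd)
  hu[bone] <- params$bone_hu
  smean <- params$sat_hu_mean + stats::rnorm(1, 0, params$subject_hu_sd)
  vmean <- params$vat_hu_mean + stats::rnorm(1, 0, params$subject_hu_sd) +
    if (group == "B") params$group_hu_shift else 0
  hu[marrow] <- rtruncnorm(sum(marrow), smean, params$sat_hu_sd,
                           w$lower, w$upper)
  hu[lung] <- params$lung_hu + stats::rnorm(sum(lung), 0, 30)
  hu[sat] <- rtruncnorm(sum(sat), smean, params$sat_hu_sd, w$lower, w$upper)
  hu[vat] <- rtruncnorm(sum(vat), vmean, params$vat_hu_sd, w$lower, w$upper)
  volume <- image_volume(hu, sp, z_origin = 0)

  # -- realized truth -------------------------------------------------------
  voxvol <- prod(sp); pixarea <- sp[1] * sp[2]
  grid_s <- half_level_positions(length(landmarks$z))
  lvl_slice <- vapply(grid_s$s, function(s)
    which.min(abs(zs - true_z_of_s(landmarks, s))), integer(1))
  level_table <- data.frame(
    label = grid_s$label, s = grid_s$s, slice = lvl_slice,
    sat_area_mm2 = vapply(lvl_slice, function(k) sum(sat[, , k]) * pixarea, 0),
    vat_area_mm2 = vapply(lvl_slice, function(k) sum(vat[, , k]) * pixarea, 0),
    stringsAsFactors = FALSE)
  truth <- list(
    sat = sat, vat = vat, body = body, soft = body & !(sat | vat | lung | bone | marrow),
    group = group,
    bmi = min(max(22 + 8 * (amp_s / 4800 - 1) + stats::rnorm(1, 0, 2.5), 16), 45),
    sat_volume_mm3 = sum(sat[, , trim]) * voxvol,
    vat_volume_mm3 = sum(vat[, , trim]) * voxvol,
    trim_range = c(lo, hi),
    level_table = level_table,
    coupled_slice = c(SAT = ps$k_star, VAT = pv$k_star),
    amp = c(SAT = amp_s, VAT = amp_v),
    marrow_voxels = sum(marrow))
  structure(list(subject_id = subject_id, volume = volume,
                 body_mask = body, lung_mask = lung, bone_mask = bone,
                 interface_mask = iface, landmarks = landmarks, truth = truth),
            class = "synthetic_subject")
}

half_level_positions <- function(n_labels,
                                 labels = default_landmark_labels()) {
  model <- structure(list(labels = labels[seq_len(n_labels)],
                          M = nominal_nodes(n_labels), n_refs = 0),
                     class = "sas_model")
  sas_half_level_grid(model)
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject> %s (group %s): ", x$subject_id, x$truth$group))
  print(x$volume)
  invisible(x)
}

#' Generate a synthetic phantom cohort
#'
#' Draws `params$n_subjects` independent subjects.  Identical
#' `params` (including `seed`) reproduce a bit-identical cohort; group
#' labels alternate A/B so both groups are balanced.  Each subject also
#' carries companion single-slice abdomen and thigh phantoms whose fat
#' areas are stochastically tied to the subject's chest fat scales
#' (yielding the modest chest-to-abdomen and weak chest-to-thigh
#' correlations typical of real cohorts).
#'
#' @param params a [phantom_params].
#' @param with_companions also generate abdomen/thigh single-slice
#'   phantoms per subject (default TRUE).
#' @return list of `synthetic_subject` objects, with the parameter set
#'   attached as attribute `params`.
#' @export
generate_cohort <- function(params = phantom_params(), with_companions = TRUE) {
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  set.seed(as.integer(params$seed) %% .Machine$integer.max)
  n <- params$n_subjects
  seeds <- sample.int(2^31 - 2, 3 * n)
  ids <- sprintf("s%03d", seq_len(n))
  groups <- rep_len(c("A", "B"), n)
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    subj <- generate_subject(params, ids[i], groups[i], seeds[i])
    if (with_companions) {
      subj$abdomen <- generate_single_slice_phantom(
        "abdomen", params, seed = seeds[n + i],
        sat_area = subj$truth$amp[["SAT"]] * 1.4 * exp(stats::rnorm(1, 0, 0.30)),
        vat_area = subj$truth$amp[["VAT"]] * 1.5 * exp(stats::rnorm(1, 0, 0.30)))
      subj$thigh <- generate_single_slice_phantom(
        "thigh", params, seed = seeds[2 * n + i],
        sat_area = subj$truth$amp[["SAT"]] * 0.5 * exp(stats::rnorm(1, 0, 0.6)),
        vat_area = subj$truth$amp[["VAT"]] * 0.15 * exp(stats::rnorm(1, 0, 0.8)))
    }
    cohort[[i]] <- subj
  }
  attr(cohort, "params") <- params
  cohort
}

#' Generate a single-slice abdomen or thigh phantom
#'
#' One 2D HU slice with body, interface and truth SAT/VAT masks.  The
#' abdomen interface emulates the interior of the abdominal wall
#' musculature; the thigh interface a fascial boundary around the
#' muscle compartment, with a femur (cortical ring plus fatty marrow
#' core) exercising the pseudo-fat correction.  `vat_area = 0` yields an
#' empty truth VAT mask.
#'
#' @param region `"abdomen"` or `"thigh"`.
#' @param params a [phantom_params] (HU distributions and spacing reused).
#' @param seed integer seed.
#' @param sat_area,vat_area target truth areas in mm^2.
#' @return list with `volume` (single-slice [image_volume]), `body_mask`,
#'   `interface_mask`, `bone_mask`, and `truth` (sat/vat masks and target
#'   areas).
#' @export
generate_single_slice_phantom <- function(region = c("abdomen", "thigh"),
                                          params = phantom_params(),
                                          seed = 1,
                                          sat_area = 6000, vat_area = 1500) {
  region <- match.arg(region)
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  d <- params$grid_shape; sp <- params$spacing
  nx <- d[1]; ny <- d[2]
  xs <- (seq_len(nx) - (nx + 1) / 2) * sp[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * sp[2]
  X <- matrix(xs, nx, ny); Y <- matrix(ys, nx, ny, byrow = TRUE)
  pixarea <- sp[1] * sp[2]

  if (region == "abdomen") {
    rx <- min(120, (nx / 2 - 1.5) * sp[1]); ry <- min(95, (ny / 2 - 1.5) * sp[2])
    f_int <- 0.70
  } else {
    rx <- min(80, (nx / 2 - 1.5) * sp[1]); ry <- min(80, (ny / 2 - 1.5) * sp[2])
    f_int <- 0.75
  }
  E <- (X / rx)^2 + (Y / ry)^2
  body <- E <= 1
  sat_area <- min(max(sat_area, 0), 0.85 * pi * rx * ry * (1 - f_int^2))
  s_in <- sqrt(1 - sat_area / (pi * rx * ry))
  sat <- E <= 1 & E > s_in^2
  iface <- E <= f_int^2

  bone <- marrow <- array(FALSE, c(nx, ny))
  if (region == "abdomen") {
    # vertebral body: cortical ring with a marrow core, posterior midline
    bc <- c(0, 0.45 * ry); br <- 14
    R2 <- (X - bc[1])^2 + (Y - bc[2])^2
    bone <- R2 <= br^2 & R2 > (0.55 * br)^2
    marrow <- R2 <= (0.55 * br)^2
    blob_center <- c(0, -0.25 * ry * f_int); aspect <- 1.9
    max_b <- 0.28 * ry * f_int
  } else {
    # femur: cortical ring with fatty marrow core, central
    R2 <- X^2 + Y^2
    bone <- R2 <= 15^2 & R2 > 7^2
    marrow <- R2 <= 7^2
    blob_center <- c(0.45 * rx * f_int, 0); aspect <- 1.2
    max_b <- 0.25 * ry * f_int
  }
  vat <- array(FALSE, c(nx, ny))
  if (vat_area > 0) {
    b <- min(sqrt(vat_area / (pi * aspect)), max_b); a <- aspect * b
    vat <- (((X - blob_center[1]) / a)^2 + ((Y - blob_center[2]) / b)^2) <= 1 &
      iface & !bone & !marrow
  }
  sat <- sat & !bone & !marrow

  w <- params$window
  hu <- matrix(-1000, nx, ny)
  hu[body] <- stats::rnorm(sum(body), params$soft_tissue_hu_mean,
                           params$soft_tissue_hu_sd)
  hu[bone] <- params$bone_hu
  hu[marrow] <- rtruncnorm(sum(marrow), params$sat_hu_mean, params$sat_hu_sd,
                           w$lower, w$upper)
  hu[sat] <- rtruncnorm(sum(sat), params$sat_hu_mean, params$sat_hu_sd,
                        w$lower, w$upper)
  hu[vat] <- rtruncnorm(sum(vat), params$vat_hu_mean, params$vat_hu_sd,
                        w$lower, w$upper)
  dim(hu) <- c(nx, ny, 1)
  tomask <- function(m) { dim(m) <- c(nx, ny, 1); m }
  list(region = region,
       volume = image_volume(hu, sp, z_origin = 0),
       body_mask = tomask(body),
       interface_mask = tomask(iface),
       bone_mask = tomask(bone),
       truth = list(sat = tomask(sat), vat = tomask(vat),
                    sat_area_target_mm2 = sat_area,
                    vat_area_target_mm2 = vat_area,
                    sat_area_mm2 = sum(sat) * pixarea,
                    vat_area_mm2 = sum(vat) * pixarea))
}

#' Simulate a cohort measurement table directly from the coupling model
#'
#' The statistical core of the phantom without voxelization: per-subject
#' compartment volumes and per-half-level areas following exactly the
#' planted coupling model (coupled level proportional to volume with
#' relative noise `coupling_noise`; other levels with independent
#' relative noise `area_noise`), plus BMI and abdomen/thigh areas tied to
#' the chest scales.  Used where many cohorts are needed cheaply (e.g.
#' best-slice recovery studies); the voxel generator uses the same model
#' for its truth profiles.
#'
#' @param params a [phantom_params].
#' @return a [cohort_table]; planted labels attached as attribute
#'   `planted`.
#' @export
simulate_cohort_table <- function(params = phantom_params()) {
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  set.seed(as.integer(params$seed) %% .Machine$integer.max)
  n <- params$n_subjects
  nlab <- length(params$landmark_labels)
  grid <- half_level_positions(nlab, params$landmark_labels)
  L <- nrow(grid)
  planted <- planted_labels(params)
  shape <- 1 + 0.12 * cos(2 * pi * (grid$s - 0.5))

  areas <- list(SAT = matrix(NA_real_, n, L), VAT = matrix(NA_real_, n, L))
  colnames(areas$SAT) <- colnames(areas$VAT) <- grid$label
  vols <- data.frame(SV_C = numeric(n), VV_C = numeric(n))
  amp_mu <- c(SAT = 4800, VAT = 1500)
  heff <- c(SAT = 150, VAT = 80)
  sub <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                    group = rep_len(c("A", "B"), n),
                    bmi = NA_real_, SA_A = NA_real_, VA_A = NA_real_,
                    SA_T = NA_real_, VA_T = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    for (cp in c("SAT", "VAT")) {
      amp <- amp_mu[[cp]] * exp(stats::rnorm(1, 0, 0.3))
      V <- amp * heff[[cp]] * exp(stats::rnorm(1, 0, 0.05))
      a <- amp * shape * (1 + stats::rnorm(L, 0, params$area_noise))
      star <- which(grid$label == planted[[cp]])
      a[star] <- V * COUPLING_C[[cp]] *
        (1 + stats::rnorm(1, 0, params$coupling_noise))
      areas[[cp]][i, ] <- pmax(a, 0)
      vols[[if (cp == "SAT") "SV_C" else "VV_C"]][i] <- V
      if (cp == "SAT") {
        sub$bmi[i] <- 22 + 8 * (amp / amp_mu[["SAT"]] - 1) + stats::rnorm(1, 0, 2.5)
        sub$SA_A[i] <- amp * 1.4 * exp(stats::rnorm(1, 0, 0.30))
        sub$SA_T[i] <- amp * 0.5 * exp(stats::rnorm(1, 0, 0.6))
      } else {
        sub$VA_A[i] <- amp * 1.5 * exp(stats::rnorm(1, 0, 0.30))
        sub$VA_T[i] <- amp * 0.15 * exp(stats::rnorm(1, 0, 0.8))
      }
    }
  }
  out <- cohort_table(sub, vols, areas)
  attr(out, "planted") <- planted
  out
}
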