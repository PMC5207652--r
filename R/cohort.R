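# End-to-end subject processing: trim -> segment -> SAS-map -> measure,
# and assembly of the cohort measurement table consumed by the
# correlation machinery.

#' Process one subject through the measurement pipeline
#'
#' Trims the volume to the standardized thoracic region, segments body /
#' fat / VAT / SAT, computes the skeletal normalizing length, maps every
#' standardized half-level to an acquired slice, and measures normalized
#' volumes, per-level areas and attenuation histograms.  Companion
#' abdomen/thigh single-slice phantoms, when present, are segmented with
#' the same operators in 2D and normalized by the same chest L.
#'
#' @param subject a `synthetic_subject` (or any list with `volume`,
#'   `lung_mask`, `interface_mask`, `bone_mask`, `landmarks`).
#' @param model a calibrated [sas_calibrate] model.
#' @param window a [fat_window].
#' @param opening_radius VAT opening radius (voxels).
#' @param body_threshold HU threshold for body segmentation.
#' @return list with the trimmed data, segmentation masks, `L`, and a
#'   `measurements` list (volumes, per-level areas, histograms,
#'   single-slice regions).
#' @export
process_subject <- function(subject, model, window = fat_window(),
                            opening_radius = 1, body_threshold = -300) {
  tr <- trim_thoracic_region(subject$volume, subject$lung_mask,
                             masks = list(interface = subject$interface_mask,
                                          bone = subject$bone_mask))
  vol <- tr$volume
  seg <- segment_subject(vol, tr$masks$interface, tr$masks$bone,
                         window = window, opening_radius = opening_radius,
                         body_threshold = body_threshold)
  L <- skeletal_diagonal(tr$masks$bone, vol$spacing)
  grid <- sas_half_level_grid(model)
  slice_grid <- slice_positions(vol)
  slices <- from_sas(subject$landmarks, model, grid$s, slice_grid,
                     subject_id = subject$subject_id %||% "subject")

  comp_masks <- list(SAT = seg$sat, VAT = seg$vat)
  vols <- lapply(names(comp_masks), function(cp)
    measure_compartment(comp_masks[[cp]], vol, L, scope = "volume",
                        subject_id = subject$subject_id, compartment = cp))
  names(vols) <- names(comp_masks)
  areas <- lapply(names(comp_masks), function(cp)
    lapply(seq_along(slices), function(j)
      suppressMessages(
        measure_compartment(comp_masks[[cp]], vol, L, scope = "slice",
                            slice = slices[j], subject_id = subject$subject_id,
                            compartment = cp))))
  names(areas) <- names(comp_masks)

  single <- list()
  for (rg in c("abdomen", "thigh")) {
    ph <- subject[[rg]]
    if (is.null(ph)) next
    body2 <- segment_body(ph$volume, body_threshold)
    fat2 <- segment_fat(ph$volume, body2, window)
    fat2 <- remove_marrow_pseudofat(fat2, ph$bone_mask)
    vat2 <- segment_vat(ph$volume, ph$interface_mask, window, opening_radius)
    vat2 <- remove_marrow_pseudofat(vat2, ph$bone_mask) & fat2
    sat2 <- segment_sat(fat2, vat2)
    single[[rg]] <- list(
      SAT = suppressMessages(
        measure_compartment(sat2, ph$volume, L, scope = "slice", slice = 1,
                            subject_id = subject$subject_id,
                            compartment = "SAT", region = rg)),
      VAT = suppressMessages(
        measure_compartment(vat2, ph$volume, L, scope = "slice", slice = 1,
                            subject_id = subject$subject_id,
                            compartment = "VAT", region = rg)))
  }

  list(subject_id = subject$subject_id, trimmed = tr, segmentation = seg,
       L = L, grid = grid, slices = slices,
       measurements = list(volumes = vols, areas = areas, single = single))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a cohort measurement table
#'
#' Calibrates the SAS model on the first `n_calibration` subjects'
#' landmarks, processes every subject with [process_subject], and packs
#' normalized volumes, per-half-level areas, histogram summaries, BMI
#' and group labels into a [cohort_table].
#'
#' @param cohort list of `synthetic_subject`s from [generate_cohort].
#' @param model optional pre-calibrated model; calibrated from the cohort
#'   when NULL.
#' @param n_calibration number of subjects used for calibration.
#' @inheritParams process_subject
#' @return a [cohort_table]; the model and per-subject processing results
#'   are attached as attributes `model` and `processed`.
#' @export
build_cohort_table <- function(cohort, model = NULL, n_calibration = 20,
                               window = fat_window(), opening_radius = 1,
                               body_threshold = -300) {
  n <- length(cohort)
  if (is.null(model)) {
    refs <- lapply(cohort[seq_len(min(n_calibration, n))], `[[`, "landmarks")
    model <- sas_calibrate(refs)
  }
  proc <- lapply(cohort, process_subject, model = model, window = window,
                 opening_radius = opening_radius,
                 body_threshold = body_threshold)
  labels <- proc[[1]]$grid$label
  L <- length(labels)
  hp <- hist_params()
  areas <- list(SAT = matrix(0, n, L, dimnames = list(NULL, labels)),
                VAT = matrix(0, n, L, dimnames = list(NULL, labels)))
  slice_hist <- list(SAT = array(NA_real_, c(n, L, 5), dimnames = list(NULL, labels, hp)),
                     VAT = array(NA_real_, c(n, L, 5), dimnames = list(NULL, labels, hp)))
  vol_hist <- list(SAT = matrix(NA_real_, n, 5, dimnames = list(NULL, hp)),
                   VAT = matrix(NA_real_, n, 5, dimnames = list(NULL, hp)))
  vols <- data.frame(SV_C = numeric(n), VV_C = numeric(n))
  sub <- data.frame(subject_id = vapply(cohort, function(s) s$subject_id %||% NA_character_, ""),
                    group = vapply(cohort, function(s) s$truth$group %||% NA_character_, ""),
                    bmi = vapply(cohort, function(s) s$truth$bmi %||% NA_real_, 0),
                    SA_A = NA_real_, VA_A = NA_real_, SA_T = NA_real_, VA_T = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    m <- proc[[i]]$measurements
    vols$SV_C[i] <- m$volumes$SAT$normalized
    vols$VV_C[i] <- m$volumes$VAT$normalized
    for (cp in c("SAT", "VAT")) {
      if (!is.null(m$volumes[[cp]]$histogram))
        vol_hist[[cp]][i, ] <- unlist(m$volumes[[cp]]$histogram[hp])
      for (j in seq_len(L)) {
        rec <- m$areas[[cp]][[j]]
        areas[[cp]][i, j] <- rec$normalized
        if (!is.null(rec$histogram))
          slice_hist[[cp]][i, j, ] <- unlist(rec$histogram[hp])
      }
    }
    if (!is.null(m$single$abdomen)) {
      sub$SA_A[i] <- m$single$abdomen$SAT$normalized
      sub$VA_A[i] <- m$single$abdomen$VAT$normalized
    }
    if (!is.null(m$single$thigh)) {
      sub$SA_T[i] <- m$single$thigh$SAT$normalized
      sub$VA_T[i] <- m$single$thigh$VAT$normalized
    }
  }
  out <- cohort_table(sub, vols, areas, vol_hist = vol_hist,
                      slice_hist = slice_hist)
  attr(out, "model") <- model
  attr(out, "processed") <- proc
  out
}

#' Tidy measurement data frame for a cohort table
#'
#' One row per subject, compartment, region and scope, with raw and
#' normalized measures and histogram parameters, using the conventional
#' variable naming (SV_C, VA_A, SVH_C_m, ...).
#'
#' @param cohort a [cohort_table].
#' @return data.frame suitable for CSV export.
#' @export
cohort_measurements_df <- function(cohort) {
  n <- nrow(cohort$subjects)
  rows <- list()
  hp <- hist_params()
  for (i in seq_len(n)) {
    for (cp in c("SAT", "VAT")) {
      vh <- if (!is.null(cohort$vol_hist)) cohort$vol_hist[[cp]][i, ] else rep(NA_real_, 5)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = cohort$subjects$subject_id[i], compartment = cp,
        region = "chest", scope = "volume",
        normalized = cohort$volumes[[volume_column(cp)]][i],
        t(stats::setNames(vh, paste0("H_", sub_param(hp)))),
        stringsAsFactors = FALSE)
      for (j in seq_along(cohort$labels)) {
        sh <- if (!is.null(cohort$slice_hist)) cohort$slice_hist[[cp]][i, j, ]
              else rep(NA_real_, 5)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = cohort$subjects$subject_id[i], compartment = cp,
          region = "chest", scope = paste0("slice@", cohort$labels[j]),
          normalized = cohort$areas[[cp]][i, j],
          t(stats::setNames(sh, paste0("H_", sub_param(hp)))),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
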