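# Thoracic SAT/VAT segmentation: region trimming, body segmentation with
# cavity filling, fat-window thresholding, interface-guided VAT extraction
# with per-slice opening, SAT by subtraction, and marrow pseudo-fat removal.

#' Fat attenuation window
#'
#' The closed Hounsfield-unit interval regarded as adipose tissue.  The
#' default `[-170, -40]` HU is the standard CT fat window; both endpoints
#' are included.
#'
#' @param lower lower bound in HU.
#' @param upper upper bound in HU.
#' @return object of class `fat_window`.
#' @export
fat_window <- function(lower = -170, upper = -40) {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("fat window requires finite lower < upper")
  structure(list(lower = lower, upper = upper), class = "fat_window")
}

#' Trim a volume to the standardized thoracic region
#'
#' The thoracic body region is defined from 15 mm superior to the lung
#' apex to 5 mm inferior to the lung base.  Margins are converted to whole
#' slices by rounding outward (`ceiling(mm / dz)`) and clipped to the
#' acquired extent; no slice is ever resampled.
#'
#' @param volume an [image_volume].
#' @param lung_mask logical array on the volume grid marking lung voxels.
#' @param masks optional named list of companion masks to crop identically.
#' @param superior_mm,inferior_mm margins in mm beyond apex/base.
#' @return list with elements `volume` (cropped [image_volume]), `masks`
#'   (cropped companions), and `slice_range` (retained 1-based index range
#'   in the input volume).
#' @export
trim_thoracic_region <- function(volume, lung_mask, masks = list(),
                                 superior_mm = 15, inferior_mm = 5) {
  check_same_grid(volume, lung_mask, "volume and lung mask")
  lung_per_slice <- apply(lung_mask, 3, any)
  if (!any(lung_per_slice)) stop("lung mask is empty; cannot trim thoracic region")
  dz <- volume$spacing[3]
  base_idx <- which(lung_per_slice)[1]            # most caudal lung slice
  apex_idx <- rev(which(lung_per_slice))[1]       # most cranial lung slice
  nz <- dim(volume$values)[3]
  lo <- max(1L, base_idx - as.integer(ceiling(inferior_mm / dz)))
  hi <- min(nz, apex_idx + as.integer(ceiling(superior_mm / dz)))
  keep <- lo:hi
  out_vol <- image_volume(volume$values[, , keep, drop = FALSE], volume$spacing,
                          z_origin = volume$z_origin + (lo - 1) * dz)
  cropped <- lapply(masks, function(m) {
    check_same_grid(volume, m, "volume and companion mask")
    as_mask(m[, , keep, drop = FALSE])
  })
  list(volume = out_vol,
       masks = c(list(lung = as_mask(lung_mask[, , keep, drop = FALSE])), cropped),
       slice_range = c(lo, hi))
}

#' Segment the body region
#'
#' Voxels above a soft-tissue/air threshold form the initial body mask;
#' interior air cavities (below-threshold regions not 4-connected to the
#' lateral slice border, treated per axial slice) are then filled so the
#' lungs and airways belong to the body region.
#'
#' @param volume an [image_volume] in HU.
#' @param threshold air/soft-tissue HU threshold (default -300).
#' @return logical body mask.
#' @export
segment_body <- function(volume, threshold = -300) {
  above <- volume$values > threshold
  dim(above) <- dim(volume$values)
  body <- fill_holes_2d(above)
  if (!any(body)) warning("body segmentation produced an empty mask")
  body
}

#' Threshold fat within the body region
#'
#' Fat voxels are body voxels whose HU value lies in the closed interval
#' `[window$lower, window$upper]`.
#'
#' @param volume an [image_volume].
#' @param body logical body mask on the same grid.
#' @param window a [fat_window].
#' @return logical fat mask.
#' @export
segment_fat <- function(volume, body, window = fat_window()) {
  check_same_grid(volume, body, "volume and body mask")
  infat <- volume$values >= window$lower & volume$values <= window$upper
  dim(infat) <- dim(volume$values)
  infat & as_mask(body)
}

#' Segment visceral adipose tissue (VAT)
#'
#' VAT is fat internal to the SAT/VAT interface (the interior surface of
#' the rib cage, pre-clipped at the diaphragm so no abdominal visceral fat
#' is included).  The thresholded mask is cleaned with a per-slice
#' morphological opening to remove isolated pixels.
#'
#' @param volume an [image_volume].
#' @param interface_mask logical mask of the thoracic-cavity interior.
#' @param window a [fat_window].
#' @param opening_radius disc radius (voxels) of the per-slice opening;
#'   0 disables the opening.
#' @return logical VAT mask.
#' @export
segment_vat <- function(volume, interface_mask, window = fat_window(),
                        opening_radius = 1) {
  check_same_grid(volume, interface_mask, "volume and interface mask")
  raw <- segment_fat(volume, interface_mask, window)
  open_mask(raw, opening_radius)
}

#' Segment subcutaneous adipose tissue (SAT) by subtraction
#'
#' SAT is the total fat mass minus the VAT component; disjointness of the
#' two compartments is guaranteed by construction.
#'
#' @param fat logical total-fat mask.
#' @param vat logical VAT mask on the same grid.
#' @return logical SAT mask.
#' @export
segment_sat <- function(fat, vat) {
  check_same_grid(fat, vat, "fat and VAT masks")
  as_mask(fat) & !as_mask(vat)
}

#' Remove marrow pseudo-fat
#'
#' Medullary bone contains voxels whose attenuation falls in the fat
#' window (pseudo fat).  The correction removes, from a fat mask, all
#' voxels inside the morphologically closed bone regions: the per-slice
#' closing bridges the cortical shell across medullary cavities (up to
#' twice the closing radius wide) without extending the skeleton
#' outward into genuine adjacent fat.
#'
#' @param mask logical fat (or SAT) mask.
#' @param bone_mask logical skeletal (cortical) mask on the same grid.
#' @param closing_radius disc radius (voxels) of the per-slice closing
#'   applied to the bone mask.
#' @return corrected logical mask.
#' @export
remove_marrow_pseudofat <- function(mask, bone_mask, closing_radius = 2) {
  mask <- as_mask(mask)
  if (!any(bone_mask)) return(mask)
  check_same_grid(mask, bone_mask, "fat and bone masks")
  bone_solid <- close_mask(as_mask(bone_mask), closing_radius)
  mask & !bone_solid
}

#' Full SAT/VAT segmentation of one subject
#'
#' Convenience wrapper running the whole chain: body segmentation, fat
#' thresholding, marrow pseudo-fat correction, interface-guided VAT
#' extraction, and SAT by subtraction.
#'
#' @param volume an [image_volume] (already trimmed to the thoracic region).
#' @param interface_mask thoracic-cavity interior mask (pre-clipped at the
#'   diaphragm).
#' @param bone_mask skeletal mask (may be all-FALSE to skip marrow
#'   correction).
#' @param window a [fat_window].
#' @param opening_radius per-slice opening radius for VAT.
#' @param body_threshold HU threshold for [segment_body].
#' @param marrow_correction apply [remove_marrow_pseudofat] to the fat mask
#'   before the SAT/VAT split (default TRUE).
#' @return list with logical masks `body`, `fat`, `vat`, `sat`.
#' @export
segment_subject <- function(volume, interface_mask, bone_mask = NULL,
                            window = fat_window(), opening_radius = 1,
                            body_threshold = -300, marrow_correction = TRUE) {
  body <- segment_body(volume, body_threshold)
  fat <- segment_fat(volume, body, window)
  vat <- segment_vat(volume, interface_mask, window, opening_radius)
  if (marrow_correction && !is.null(bone_mask) && any(bone_mask)) {
    fat <- remove_marrow_pseudofat(fat, bone_mask)
    vat <- remove_marrow_pseudofat(vat, bone_mask)
  }
  vat <- vat & fat  # opening can only shrink; keep VAT inside the fat mass
  sat <- segment_sat(fat, vat)
  list(body = body, fat = fat, vat = vat, sat = sat)
}
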