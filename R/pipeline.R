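# Reproducible pipeline driver: simulate -> segment -> calibrate -> map
# -> quantify -> analyze, with JSON config, stage-tagged logging, CSV/JSON
# artifacts and a checksummed run manifest.

#' Pipeline run configuration
#'
#' Bundles every tunable of a pipeline run.  Serializes losslessly to
#' JSON via [save_run_config]/[load_run_config].  Seeds are mandatory:
#' nothing in the pipeline ever seeds from the wall clock.
#'
#' @param phantom list of [phantom_params] overrides (e.g.
#'   `list(n_subjects = 12, seed = 7)`).
#' @param window_lower,window_upper fat window bounds (HU).
#' @param opening_radius VAT opening radius (voxels).
#' @param body_threshold body segmentation threshold (HU).
#' @param n_calibration subjects used for SAS calibration.
#' @param with_scc compute Spearman correlations in the report.
#' @param welch use Welch instead of pooled t-tests.
#' @param out_dir output directory.
#' @param seed run seed (overrides `phantom$seed` when given).
#' @return list of class `run_config`.
#' @export
run_config <- function(phantom = list(), window_lower = -170,
                       window_upper = -40, opening_radius = 1,
                       body_threshold = -300, n_calibration = 20,
                       with_scc = TRUE, welch = FALSE,
                       out_dir = "fatsas_run", seed = 1) {
  cfg <- list(phantom = phantom, window_lower = window_lower,
              window_upper = window_upper, opening_radius = opening_radius,
              body_threshold = body_threshold, n_calibration = n_calibration,
              with_scc = with_scc, welch = welch, out_dir = out_dir,
              seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
save_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$phantom <- as.list(raw$phantom)
  do.call(run_config, raw)
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

config_phantom_params <- function(config) {
  ph <- config$phantom
  ph$seed <- config$seed %||% ph$seed %||% 1
  ph$window <- fat_window(config$window_lower, config$window_upper)
  do.call(phantom_params, ph)
}

stage_paths <- function(out_dir) {
  list(cohort = file.path(out_dir, "cohort.rds"),
       landmarks = file.path(out_dir, "landmarks.csv"),
       truth = file.path(out_dir, "truth.csv"),
       segmentations = file.path(out_dir, "segmentations.rds"),
       model = file.path(out_dir, "sas_model.json"),
       slice_map = file.path(out_dir, "slice_map.csv"),
       measurements = file.path(out_dir, "measurements.csv"),
       cohort_table = file.path(out_dir, "cohort_table.rds"),
       correlations = file.path(out_dir, "correlations.csv"),
       best_slices = file.path(out_dir, "best_slices.csv"),
       groups = file.path(out_dir, "groups.csv"),
       precision = file.path(out_dir, "precision.csv"),
       manifest = file.path(out_dir, "manifest.json"))
}

#' Run the full pipeline
#'
#' Executes simulate, segment, calibrate, map, quantify and analyze in
#' order, writing every intermediate artifact under `config$out_dir` and
#' a manifest with per-file MD5 checksums.  The same config and seed
#' reproduce identical result CSVs.
#'
#' @param config a [run_config].
#' @return the manifest (invisibly), a list with config hash, seed and
#'   per-artifact checksums.
#' @export
run_all <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- stage_paths(config$out_dir)
  stage_simulate(config)
  stage_segment(config)
  stage_calibrate(config)
  stage_map(config)
  stage_quantify(config)
  stage_analyze(config)
  files <- unlist(paths[names(paths) != "manifest"])
  files <- files[file.exists(files)]
  manifest <- list(
    config = unclass(config),
    config_hash = unname(tools::md5sum(save_run_config(config, tempfile(fileext = ".json")))),
    seed = config$seed,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_stage("run_all", "complete; manifest at %s", paths$manifest)
  invisible(manifest)
}

require_artifact <- function(path, stage, produced_by) {
  if (!file.exists(path))
    stop(sprintf("[%s] missing upstream artifact %s (run `%s` first)",
                 stage, path, produced_by))
  path
}

#' Pipeline stages
#'
#' Each stage is runnable standalone against the on-disk artifacts of the
#' preceding stages; a missing upstream file raises an explicit
#' dependency error.
#'
#' @param config a [run_config].
#' @return the stage's primary artifact path, invisibly.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config) {
  paths <- stage_paths(config$out_dir)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- config_phantom_params(config)
  log_stage("simulate", "generating %d subjects (seed %d)",
            params$n_subjects, as.integer(params$seed))
  cohort <- generate_cohort(params)
  saveRDS(cohort, paths$cohort, version = 3)
  lm_df <- do.call(rbind, lapply(cohort, function(s)
    data.frame(subject_id = s$subject_id, label = s$landmarks$labels,
               z_mm = s$landmarks$z, stringsAsFactors = FALSE)))
  utils::write.csv(lm_df, paths$landmarks, row.names = FALSE)
  truth_df <- do.call(rbind, lapply(cohort, function(s)
    data.frame(subject_id = s$subject_id, group = s$truth$group,
               bmi = s$truth$bmi, sat_volume_mm3 = s$truth$sat_volume_mm3,
               vat_volume_mm3 = s$truth$vat_volume_mm3,
               s$truth$level_table, stringsAsFactors = FALSE)))
  utils::write.csv(truth_df, paths$truth, row.names = FALSE)
  invisible(paths$cohort)
}

read_cohort <- function(config, stage) {
  paths <- stage_paths(config$out_dir)
  readRDS(require_artifact(paths$cohort, stage, "simulate"))
}

#' @rdname pipeline_stages
#' @export
stage_segment <- function(config) {
  paths <- stage_paths(config$out_dir)
  cohort <- read_cohort(config, "segment")
  window <- fat_window(config$window_lower, config$window_upper)
  log_stage("segment", "window [%g, %g] HU, opening radius %g",
            window$lower, window$upper, config$opening_radius)
  segs <- lapply(cohort, function(s) {
    tr <- trim_thoracic_region(s$volume, s$lung_mask,
                               masks = list(interface = s$interface_mask,
                                            bone = s$bone_mask))
    seg <- segment_subject(tr$volume, tr$masks$interface, tr$masks$bone,
                           window = window,
                           opening_radius = config$opening_radius,
                           body_threshold = config$body_threshold)
    stopifnot(!any(seg$sat & seg$vat))
    list(subject_id = s$subject_id, slice_range = tr$slice_range, masks = seg)
  })
  saveRDS(segs, paths$segmentations, version = 3)
  invisible(paths$segmentations)
}

#' @rdname pipeline_stages
#' @export
stage_calibrate <- function(config) {
  paths <- stage_paths(config$out_dir)
  cohort <- read_cohort(config, "calibrate")
  refs <- lapply(cohort[seq_len(min(config$n_calibration, length(cohort)))],
                 `[[`, "landmarks")
  model <- sas_calibrate(refs)
  log_stage("calibrate", "model from %d reference subjects", model$n_refs)
  jsonlite::write_json(list(labels = model$labels, M = model$M,
                            n_refs = model$n_refs),
                       paths$model, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths$model)
}

read_model <- function(config, stage) {
  paths <- stage_paths(config$out_dir)
  raw <- jsonlite::read_json(require_artifact(paths$model, stage, "calibrate"),
                             simplifyVector = TRUE)
  structure(list(labels = raw$labels, M = raw$M, n_refs = raw$n_refs),
            class = "sas_model")
}

#' @rdname pipeline_stages
#' @export
stage_map <- function(config) {
  paths <- stage_paths(config$out_dir)
  cohort <- read_cohort(config, "map")
  model <- read_model(config, "map")
  grid <- sas_half_level_grid(model)
  rows <- lapply(cohort, function(s) {
    tr <- trim_thoracic_region(s$volume, s$lung_mask)
    sg <- slice_positions(tr$volume)
    idx <- from_sas(s$landmarks, model, grid$s, sg, subject_id = s$subject_id)
    data.frame(subject_id = s$subject_id, label = grid$label, s = grid$s,
               slice = idx, z_mm = sg[idx], stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), paths$slice_map, row.names = FALSE)
  log_stage("map", "mapped %d standardized levels for %d subjects",
            nrow(grid), length(cohort))
  invisible(paths$slice_map)
}

#' @rdname pipeline_stages
#' @export
stage_quantify <- function(config) {
  paths <- stage_paths(config$out_dir)
  cohort <- read_cohort(config, "quantify")
  model <- read_model(config, "quantify")
  window <- fat_window(config$window_lower, config$window_upper)
  tab <- build_cohort_table(cohort, model = model,
                            window = window,
                            opening_radius = config$opening_radius,
                            body_threshold = config$body_threshold)
  attr(tab, "processed") <- NULL       # keep the on-disk artifact lean
  saveRDS(tab, paths$cohort_table, version = 3)
  utils::write.csv(cohort_measurements_df(tab), paths$measurements,
                   row.names = FALSE)
  log_stage("quantify", "measured %d subjects at %d levels",
            nrow(tab$subjects), length(tab$labels))
  invisible(paths$measurements)
}

#' @rdname pipeline_stages
#' @export
stage_analyze <- function(config) {
  paths <- stage_paths(config$out_dir)
  tab <- readRDS(require_artifact(paths$cohort_table, "analyze", "quantify"))
  if (nrow(tab$subjects) < 8)
    warning("analyze: fewer than 8 subjects; best-slice search is unstable")
  rep <- correlation_report(tab, with_scc = config$with_scc)
  utils::write.csv(rep, paths$correlations, row.names = FALSE)
  best <- attr(rep, "best_slices")
  bs_df <- do.call(rbind, lapply(c("SAT", "VAT"), function(cp)
    do.call(rbind, lapply(best[[cp]], function(b)
      data.frame(compartment = cp, k = b$k,
                 labels = paste(b$labels, collapse = "+"),
                 rho = b$rho, stringsAsFactors = FALSE)))))
  utils::write.csv(bs_df, paths$best_slices, row.names = FALSE)
  grp <- group_comparison_table(tab, welch = config$welch)
  utils::write.csv(grp, paths$groups, row.names = FALSE)
  prec <- segmentation_precision_table(config)
  utils::write.csv(prec, paths$precision, row.names = FALSE)
  log_stage("analyze", "best SAT slice %s (rho %.3f), best VAT slice %s (rho %.3f)",
            best$SAT[[1]]$labels, best$SAT[[1]]$rho,
            best$VAT[[1]]$labels, best$VAT[[1]]$rho)
  invisible(paths$correlations)
}

#' Group comparison table for a cohort
#'
#' Compares normalized volumes, best-slice areas and VAT attenuation
#' histogram parameters between the two group labels with unpaired
#' t-tests and Mann-Whitney U tests.
#'
#' @param cohort a [cohort_table] with a `group` column.
#' @param welch use Welch t-tests.
#' @return data.frame (variable, per-group mean and SD, p values).
#' @export
group_comparison_table <- function(cohort, welch = FALSE) {
  g <- cohort$subjects$group
  lv <- sort(unique(g))
  if (length(lv) != 2) stop("group comparison requires exactly 2 group labels")
  ia <- g == lv[1]; ib <- g == lv[2]
  vars <- list(SV_C = cohort$volumes$SV_C, VV_C = cohort$volumes$VV_C)
  if (!is.null(cohort$vol_hist))
    for (p in hist_params())
      vars[[paste0("VVH_C_", sub_param(p))]] <- cohort$vol_hist$VAT[, p]
  best_vat <- best_slices(cohort, "VAT", 1)
  if (!is.null(cohort$slice_hist))
    for (p in hist_params())
      vars[[paste0("VAH_C_", sub_param(p))]] <-
        cohort$slice_hist$VAT[, cohort$labels == best_vat$labels, p]
  rows <- lapply(names(vars), function(v) {
    x <- vars[[v]]
    if (anyNA(x)) return(NULL)
    gc <- group_compare(x[ia], x[ib], variable = v, welch = welch)
    data.frame(variable = v,
               mean_a = gc$mean_a, sd_a = gc$sd_a,
               mean_b = gc$mean_b, sd_b = gc$sd_b,
               p_t = gc$p_t, p_mwu = gc$p_mwu, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Repeatability emulation: the interactive interface delineation is the
# operator-dependent step, so repeated "trials" perturb the interface
# (intra: morphological erosion by 1 voxel of the interface; inter:
# additionally a 1-voxel dilation) and the Jaccard overlap of the
# resulting compartment masks is reported per region and compartment.
segmentation_precision_table <- function(config, n_subjects = 3) {
  cohort <- read_cohort(config, "analyze")
  cohort <- cohort[seq_len(min(n_subjects, length(cohort)))]
  window <- fat_window(config$window_lower, config$window_upper)
  rows <- list()
  for (s in cohort) {
    tr <- trim_thoracic_region(s$volume, s$lung_mask,
                               masks = list(interface = s$interface_mask,
                                            bone = s$bone_mask))
    variants <- list(base = tr$masks$interface,
                     intra = erode_mask(tr$masks$interface, 1),
                     inter = dilate_mask(tr$masks$interface, 1))
    segs <- lapply(variants, function(im)
      segment_subject(tr$volume, im, tr$masks$bone, window = window,
                      opening_radius = config$opening_radius,
                      body_threshold = config$body_threshold))
    for (cp in c("sat", "vat")) {
      rows[[length(rows) + 1]] <- data.frame(
        region = "chest", compartment = toupper(cp),
        subject_id = s$subject_id,
        intra = jaccard_precision(segs$base[[cp]], segs$intra[[cp]]),
        inter = jaccard_precision(segs$base[[cp]], segs$inter[[cp]]),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  stats::aggregate(cbind(intra, inter) ~ region + compartment, df, mean)
}

#' Command-line entry point
#'
#' Dispatches `fatsas <stage> [--config run.json] [--seed N] [--out DIR]`
#' where `<stage>` is one of `run_all`, `simulate`, `segment`,
#' `calibrate`, `map`, `quantify`, `analyze`.
#'
#' @param args character vector of CLI arguments.
#' @return exit status (0 on success), invisibly.
#' @export
fatsas_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages <- c(run_all = run_all, simulate = stage_simulate,
              segment = stage_segment, calibrate = stage_calibrate,
              map = stage_map, quantify = stage_quantify,
              analyze = stage_analyze)
  if (length(args) < 1 || !(args[1] %in% names(stages))) {
    message("usage: fatsas <", paste(names(stages), collapse = "|"),
            "> [--config run.json] [--seed N] [--out DIR]")
    return(invisible(1L))
  }
  stage <- args[1]; rest <- args[-1]
  getopt <- function(flag) {
    i <- which(rest == flag)
    if (length(i) == 1 && i < length(rest)) rest[i + 1] else NULL
  }
  cfg <- if (!is.null(getopt("--config"))) load_run_config(getopt("--config"))
         else run_config()
  if (!is.null(getopt("--seed"))) cfg$seed <- as.integer(getopt("--seed"))
  if (!is.null(getopt("--out"))) cfg$out_dir <- getopt("--out")
  stages[[stage]](cfg)
  invisible(0L)
}
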