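# Cohort-level statistics: Pearson/Spearman correlation, the exhaustive
# best-slice search on the standardized half-level grid, the Jaccard
# repeatability metric, and two-group comparisons.

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation (n-1 covariance convention; the factor
#' cancels in the ratio).  Constant input is an error, not NA, so silent
#' degenerate columns cannot leak into a report.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param names variable names used in error messages.
#' @return correlation in `[-1, 1]`.
#' @export
pcc <- function(x, y, names = c("x", "y")) {
  if (length(x) != length(y)) stop("pcc: input lengths differ")
  if (length(x) < 3) stop("pcc: need at least 3 observations")
  if (stats::sd(x) == 0) stop(sprintf("pcc: variable '%s' is constant", names[1]))
  if (stats::sd(y) == 0) stop(sprintf("pcc: variable '%s' is constant", names[2]))
  stats::cor(x, y)
}

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of average ranks (ties share their mean rank).
#'
#' @inheritParams pcc
#' @return correlation in `[-1, 1]`.
#' @export
scc <- function(x, y, names = c("x", "y")) {
  if (length(x) != length(y)) stop("scc: input lengths differ")
  if (length(x) < 3) stop("scc: need at least 3 observations")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0) stop(sprintf("scc: variable '%s' is constant", names[1]))
  if (stats::sd(ry) == 0) stop(sprintf("scc: variable '%s' is constant", names[2]))
  stats::cor(rx, ry)
}

#' Jaccard precision between two segmentations
#'
#' Repeatability metric for repeated segmentations of the same object:
#' `|S1 n S2| / |S1 u S2|`.  Symmetric; equals 1 iff the masks are
#' identical and 0 iff they are disjoint.
#'
#' @param s1,s2 logical masks on the same grid.
#' @return value in `[0, 1]`.
#' @export
jaccard_precision <- function(s1, s2) {
  check_same_grid(s1, s2, "segmentation masks")
  s1 <- as_mask(s1); s2 <- as_mask(s2)
  u <- sum(s1 | s2)
  if (u == 0) stop("jaccard_precision undefined: both masks are empty")
  sum(s1 & s2) / u
}

#' Cohort measurement table
#'
#' The container consumed by every correlation and group statistic: one
#' row per subject with normalized chest volumes, normalized per-level
#' slice areas on the standardized half-level grid, optional abdomen and
#' thigh slice areas, BMI, group labels, and attenuation-histogram
#' summaries per scope.
#'
#' @param subjects data.frame with at least `subject_id`; optionally
#'   `group`, `bmi`, `SA_A`, `VA_A`, `SA_T`, `VA_T`.
#' @param volumes data.frame with normalized `SV_C` and `VV_C`.
#' @param areas named list (`SAT`, `VAT`) of n-by-L matrices of normalized
#'   areas, columns named by half-level labels (identical across
#'   compartments).
#' @param vol_hist optional named list (`SAT`, `VAT`) of n-by-5 matrices of
#'   whole-volume histogram parameters (columns H_m, H_md, H_p, H_lq, H_uq).
#' @param slice_hist optional named list of n-by-L-by-5 arrays of per-level
#'   histogram parameters.
#' @return object of class `cohort_table`.
#' @export
cohort_table <- function(subjects, volumes, areas,
                         vol_hist = NULL, slice_hist = NULL) {
  n <- nrow(subjects)
  if (n < 2) stop("cohort_table: need at least 2 subjects")
  if (nrow(volumes) != n) stop("cohort_table: volumes/subjects row mismatch")
  labels <- colnames(areas$SAT)
  for (cp in names(areas)) {
    if (!identical(colnames(areas[[cp]]), labels))
      stop("cohort_table: area grid labels differ across compartments")
    if (nrow(areas[[cp]]) != n)
      stop("cohort_table: area matrix rows != number of subjects")
    if (anyNA(areas[[cp]]))
      stop("cohort_table: every subject needs a value at every grid label")
  }
  structure(list(subjects = subjects, volumes = volumes, areas = areas,
                 labels = labels, vol_hist = vol_hist, slice_hist = slice_hist),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects, %d standardized levels (%s .. %s)\n",
              nrow(x$subjects), length(x$labels), x$labels[1],
              x$labels[length(x$labels)]))
  invisible(x)
}

volume_column <- function(compartment) {
  switch(compartment, SAT = "SV_C", VAT = "VV_C",
         stop("unknown compartment: ", compartment))
}

#' Best-slice search on the standardized grid
#'
#' Exhaustively searches all combinations of `k` distinct half-level
#' labels for the set whose summed per-slice area has maximal Pearson
#' correlation with the whole-region normalized volume across subjects.
#' Combinations need not be contiguous.  Exact ties resolve to the most
#' cranial (lexicographically smallest) label tuple; labels whose areas
#' are constant across the cohort are skipped (an error if all are).
#'
#' @param cohort a [cohort_table].
#' @param compartment `"SAT"` or `"VAT"`.
#' @param k number of slices, 1, 2 or 3.
#' @return object of class `best_slice_result`: list with `k`, `labels`,
#'   `rho`, and `objective` (rho for every combination, for auditing).
#' @export
best_slices <- function(cohort, compartment = c("SAT", "VAT"), k = 1) {
  compartment <- match.arg(compartment)
  if (!k %in% 1:3) stop("k must be 1, 2 or 3")
  A <- cohort$areas[[compartment]]
  v <- cohort$volumes[[volume_column(compartment)]]
  if (nrow(A) < 4) stop("best_slices: need at least 4 subjects")
  usable <- which(apply(A, 2, stats::sd) > 0)
  if (length(usable) == 0)
    stop("best_slices: areas constant at every standardized label")
  if (stats::sd(v) == 0) stop("best_slices: volumes are constant")
  combos <- utils::combn(seq_len(ncol(A)), k)
  rho <- rep(NA_real_, ncol(combos))
  for (j in seq_len(ncol(combos))) {
    ssum <- rowSums(A[, combos[, j], drop = FALSE])
    if (stats::sd(ssum) > 0) rho[j] <- stats::cor(ssum, v)
  }
  if (all(is.na(rho)))
    stop("best_slices: every candidate combination is degenerate")
  best <- which(!is.na(rho) & rho >= max(rho, na.rm = TRUE) - 0)[1]
  structure(list(k = k, labels = cohort$labels[combos[, best]],
                 rho = rho[best],
                 objective = data.frame(
                   combo = apply(combos, 2, function(ix)
                     paste(cohort$labels[ix], collapse = "+")),
                   rho = rho)),
            class = "best_slice_result")
}

#' @export
print.best_slice_result <- function(x, ...) {
  cat(sprintf("<best_slice_result> k=%d  labels: %s  rho=%.4f\n",
              x$k, paste(x$labels, collapse = ", "), x$rho))
  invisible(x)
}

#' Two-group comparison
#'
#' Two-sided unpaired t-test (pooled variance by default, Welch optional)
#' and two-sided Mann-Whitney U test using the normal approximation with
#' tie correction.  Two constant groups with equal values yield p = 1 by
#' convention (logged as a message).
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param variable variable name carried into the result.
#' @param welch use the Welch (unequal-variance) t-test.
#' @return object of class `group_comparison`: list with group means/SDs,
#'   `p_t`, `p_mwu`.
#' @export
group_compare <- function(values_a, values_b, variable = "variable",
                          welch = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("group_compare: each group needs at least 2 values")
  degenerate <- stats::sd(values_a) == 0 && stats::sd(values_b) == 0
  if (degenerate && mean(values_a) == mean(values_b)) {
    message(sprintf("group_compare(%s): both groups constant and equal; p = 1",
                    variable))
    p_t <- 1; p_mwu <- 1; tstat <- 0
  } else if (degenerate) {
    p_t <- 0; p_mwu <- NA_real_; tstat <- Inf
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = !welch)
    p_t <- tt$p.value; tstat <- unname(tt$statistic)
    p_mwu <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = FALSE,
                         correct = FALSE)$p.value)
  }
  structure(list(variable = variable,
                 mean_a = mean(values_a), sd_a = stats::sd(values_a),
                 mean_b = mean(values_b), sd_b = stats::sd(values_b),
                 n_a = length(values_a), n_b = length(values_b),
                 t_statistic = tstat, p_t = p_t, p_mwu = p_mwu,
                 welch = welch),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %.3g +/- %.3g vs %.3g +/- %.3g,  p_t=%.3g  p_mwu=%.3g\n",
              x$variable, x$mean_a, x$sd_a, x$mean_b, x$sd_b, x$p_t, x$p_mwu))
  invisible(x)
}

hist_params <- function() c("H_m", "H_md", "H_p", "H_lq", "H_uq")

#' Cohort correlation report
#'
#' Computes the full system of correlations between normalized chest fat
#' volumes, per-level and best-slice areas, abdomen/thigh slice areas,
#' BMI, and whole-volume vs best-slice attenuation-histogram parameters.
#' Slice-derived chest variables (`SA_C`, `VA_C` and the slice histogram
#' parameters) are evaluated at the best 1-slice location for each
#' compartment; volume-to-area rows for 2 and 3 slices use the best
#' 2-/3-slice area sums.  Missing variables (e.g. no BMI) produce a row
#' flagged missing rather than an error.  No multiple-testing correction
#' is applied; raw correlations only.
#'
#' @param cohort a [cohort_table].
#' @param with_scc also compute Spearman correlations.
#' @return data.frame with columns `group`, `pair`, `rho_pcc`, `rho_scc`,
#'   `missing`; the best-slice locations used are attached as attribute
#'   `best_slices`.
#' @export
correlation_report <- function(cohort, with_scc = TRUE) {
  sub <- cohort$subjects
  getvar <- function(name) {
    if (name %in% names(sub)) sub[[name]]
    else if (name %in% names(cohort$volumes)) cohort$volumes[[name]]
    else NULL
  }
  best <- list()
  for (cp in c("SAT", "VAT"))
    best[[cp]] <- lapply(1:3, function(k) best_slices(cohort, cp, k))
  best_area <- function(cp, k) {
    labs <- best[[cp]][[k]]$labels
    rowSums(cohort$areas[[cp]][, cohort$labels %in% labs, drop = FALSE])
  }
  sa_c <- best_area("SAT", 1); va_c <- best_area("VAT", 1)

  rows <- list()
  add <- function(group, pair, x, y) {
    miss <- is.null(x) || is.null(y) || anyNA(x) || anyNA(y)
    # degenerate (constant) variables are reported as missing, not fatal
    rho_p <- if (miss) NA_real_ else
      tryCatch(pcc(x, y, strsplit(pair, ", ")[[1]]),
               error = function(e) NA_real_)
    rho_s <- if (miss || !with_scc || is.na(rho_p)) NA_real_ else scc(x, y)
    rows[[length(rows) + 1]] <<- data.frame(
      group = group, pair = pair, rho_pcc = rho_p, rho_scc = rho_s,
      missing = miss || is.na(rho_p), stringsAsFactors = FALSE)
  }

  sv <- cohort$volumes$SV_C; vv <- cohort$volumes$VV_C
  add("volume-to-area", "SV_C, SA_A", sv, getvar("SA_A"))
  add("volume-to-area", "SV_C, SA_T", sv, getvar("SA_T"))
  for (k in 1:3)
    add("volume-to-area", sprintf("SV_C, SA_C [%d sl]", k), sv, best_area("SAT", k))
  add("volume-to-area", "VV_C, VA_A", vv, getvar("VA_A"))
  add("volume-to-area", "VV_C, VA_T", vv, getvar("VA_T"))
  for (k in 1:3)
    add("volume-to-area", sprintf("VV_C, VA_C [%d sl]", k), vv, best_area("VAT", k))

  add("area-to-area", "SA_C, SA_A", sa_c, getvar("SA_A"))
  add("area-to-area", "SA_C, SA_T", sa_c, getvar("SA_T"))
  add("area-to-area", "VA_C, VA_A", va_c, getvar("VA_A"))
  add("area-to-area", "VA_C, VA_T", va_c, getvar("VA_T"))

  for (cp in c("SAT", "VAT")) {
    tagv <- if (cp == "SAT") "SVH_C" else "VVH_C"
    taga <- if (cp == "SAT") "SAH_C" else "VAH_C"
    lab1 <- best[[cp]][[1]]$labels
    for (p in hist_params()) {
      xv <- if (!is.null(cohort$vol_hist)) cohort$vol_hist[[cp]][, p] else NULL
      yv <- if (!is.null(cohort$slice_hist))
        cohort$slice_hist[[cp]][, cohort$labels == lab1, p] else NULL
      add("hist-volume-to-hist-slice",
          sprintf("%s,%s, %s,%s", tagv, sub_param(p), taga, sub_param(p)),
          xv, yv)
    }
  }

  bmi <- getvar("bmi")
  add("BMI", "BMI, SV_C", bmi, sv)
  add("BMI", "BMI, VV_C", bmi, vv)
  add("BMI", "BMI, SA_A", bmi, getvar("SA_A"))
  add("BMI", "BMI, SA_T", bmi, getvar("SA_T"))
  add("BMI", "BMI, VA_A", bmi, getvar("VA_A"))
  add("BMI", "BMI, VA_T", bmi, getvar("VA_T"))
  add("BMI", "BMI, SA_C", bmi, sa_c)
  add("BMI", "BMI, VA_C", bmi, va_c)

  out <- do.call(rbind, rows)
  attr(out, "best_slices") <- best
  out
}

sub_param <- function(p) sub("^H_", "", p)
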