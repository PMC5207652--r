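# Shared fixtures and independent brute-force oracles.  Oracles are
# deliberately written with plain voxel loops / queues, independent of the
# package's vectorized implementations.

# small, fast phantom parameterization for module tests
small_params <- function(n_subjects = 6, seed = 101, ...) {
  phantom_params(n_subjects = n_subjects, grid_shape = c(48, 48, 28),
                 spacing = c(6, 6, 7), seed = seed, ...)
}

# memoized small voxel cohort + processed table (built once per run)
.fixture_env <- new.env(parent = emptyenv())
shared_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- generate_cohort(small_params())
  .fixture_env$cohort
}
shared_table <- function() {
  if (is.null(.fixture_env$table))
    .fixture_env$table <- build_cohort_table(shared_cohort(), n_calibration = 6)
  .fixture_env$table
}

# nominal (equally spaced) standardized model for n labels
nominal_model <- function(labels = paste0("T", 2:10)) {
  structure(list(labels = labels,
                 M = seq(0, 1, length.out = length(labels)), n_refs = 0),
            class = "sas_model")
}

# random strictly increasing landmark set
random_landmarks <- function(n = 9, labels = paste0("T", 2:10)) {
  z <- sort(runif(1, 20, 80) + cumsum(runif(n, 5, 25)))
  landmark_set(z, labels[seq_len(n)])
}

# ---- voxel-loop oracles ---------------------------------------------------

oracle_threshold <- function(values, lower, upper) {
  d <- dim(values)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    out[i, j, k] <- values[i, j, k] >= lower && values[i, j, k] <= upper
  out
}

oracle_disc <- function(radius) {
  r <- as.integer(ceiling(radius))
  off <- list()
  for (dx in -r:r) for (dy in -r:r)
    if (dx^2 + dy^2 <= radius^2 + 1e-9) off[[length(off) + 1]] <- c(dx, dy)
  off
}

oracle_erode <- function(mask, radius) {
  d <- dim(mask); off <- oracle_disc(radius)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    keep <- TRUE
    for (o in off) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || !mask[ii, jj, k]) {
        keep <- FALSE; break
      }
    }
    out[i, j, k] <- keep
  }
  out
}

oracle_dilate <- function(mask, radius) {
  d <- dim(mask); off <- oracle_disc(radius)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    hit <- FALSE
    for (o in off) {
      ii <- i - o[1]; jj <- j - o[2]
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && mask[ii, jj, k]) {
        hit <- TRUE; break
      }
    }
    out[i, j, k] <- hit
  }
  out
}

oracle_open <- function(mask, radius) oracle_dilate(oracle_erode(mask, radius), radius)

# BFS per-slice hole filling (4-connectivity): background reachable from
# the lateral border stays background; the rest is filled.
oracle_fill <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    reach <- matrix(FALSE, d[1], d[2])
    queue <- list()
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      if ((i == 1 || i == d[1] || j == 1 || j == d[2]) && !sl[i, j]) {
        reach[i, j] <- TRUE; queue[[length(queue) + 1]] <- c(i, j)
      }
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- p[1] + o[1]; jj <- p[2] + o[2]
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
            !sl[ii, jj] && !reach[ii, jj]) {
          reach[ii, jj] <- TRUE; queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
    out[, , k] <- sl | (!sl & !reach)
  }
  out
}

# numeric interpolation oracle for the SAS map: stats::approx inside the
# landmark span, manual end-segment slopes outside; independent of the
# package's findInterval-based path.
oracle_to_sas <- function(subject, model, z) {
  zs <- subject$z; M <- model$M
  n <- length(zs)
  ord <- order(zs)
  vapply(z, function(zi) {
    before_first <- (zi - zs[1]) * sign(zs[n] - zs[1]) < 0
    after_last <- (zi - zs[n]) * sign(zs[n] - zs[1]) > 0
    if (before_first)
      return(M[1] + (M[2] - M[1]) / (zs[2] - zs[1]) * (zi - zs[1]))
    if (after_last)
      return(M[n] + (M[n] - M[n - 1]) / (zs[n] - zs[n - 1]) * (zi - zs[n]))
    stats::approx(zs[ord], M[ord], xout = zi)$y
  }, numeric(1))
}
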