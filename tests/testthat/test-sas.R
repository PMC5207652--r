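# Standardized anatomic space: calibration, piecewise-linear transform,
# inversion to acquired slices, the linear baseline and half-level labels.

test_that("calibration normalizes affinely and averages per landmark", {
  lm1 <- landmark_set(seq(0, 80, by = 10), paste0("T", 2:10))
  m1 <- sas_calibrate(list(lm1))
  expect_equal(m1$M, seq(0, 1, by = 1 / 8))
  # scaled/translated copies calibrate identically
  lm2 <- landmark_set(200 + 2.5 * seq(0, 80, by = 10), paste0("T", 2:10))
  expect_equal(sas_calibrate(list(lm1, lm2))$M, m1$M)
  # brute-force mean oracle over 20 random monotone sets
  set.seed(5)
  refs <- replicate(20, random_landmarks(), simplify = FALSE)
  model <- sas_calibrate(refs)
  oracle <- rowMeans(sapply(refs, function(lm)
    (lm$z - lm$z[1]) / (lm$z[9] - lm$z[1])))
  expect_equal(model$M, oracle, tolerance = 1e-12)
  expect_true(all(diff(model$M) > 0))
  lm_bad <- landmark_set(seq(0, 80, by = 10), paste0("L", 1:9))
  expect_error(sas_calibrate(list(lm1, lm_bad)), "labels")
})

test_that("to_sas interpolates at nodes, midpoints and random z against the oracle", {
  set.seed(6)
  model <- sas_calibrate(replicate(5, random_landmarks(), simplify = FALSE))
  subject <- random_landmarks()
  expect_equal(to_sas(subject, model, subject$z), model$M, tolerance = 1e-12)
  mid_z <- (subject$z[3] + subject$z[4]) / 2
  expect_equal(to_sas(subject, model, mid_z), (model$M[3] + model$M[4]) / 2,
               tolerance = 1e-12)
  zq <- runif(100, subject$z[1] - 30, subject$z[9] + 30)
  expect_equal(to_sas(subject, model, zq), oracle_to_sas(subject, model, zq),
               tolerance = 1e-9)
  # order preservation
  zq <- sort(zq)
  expect_true(all(diff(to_sas(subject, model, zq)) > 0))
})

test_that("from_sas inverts to the nearest acquired slice with cranial tie-break", {
  model <- nominal_model()
  subject <- landmark_set(seq(20, 180, length.out = 9), paste0("T", 2:10))
  grid <- seq(0, 200, by = 10)
  # round trip on grid slices
  for (k in c(3, 11, 19)) {
    s <- to_sas(subject, model, grid[k])
    expect_equal(from_sas(subject, model, s, grid), k)
  }
  expect_equal(from_sas(subject, model, 0, grid), which(grid == 20))
  # z = 25 mm sits exactly between slices at 20 and 30 -> more cranial (30)
  s_tie <- to_sas(subject, model, 25)
  expect_equal(from_sas(subject, model, s_tie, grid), which(grid == 30))
  expect_error(from_sas(subject, model, 5, grid, subject_id = "s42"), "s42")
})

test_that("round-trip inversion is exact inside the landmark span", {
  set.seed(7)
  model <- sas_calibrate(replicate(8, random_landmarks(), simplify = FALSE))
  subject <- random_landmarks()
  z <- runif(50, subject$z[1], subject$z[9])
  expect_equal(sas_invert(subject, model, to_sas(subject, model, z)), z,
               tolerance = 1e-9)
})

test_that("selected labels are invariant to affine rescaling of a subject", {
  set.seed(8)
  model <- sas_calibrate(replicate(6, random_landmarks(), simplify = FALSE))
  subject <- random_landmarks()
  grid <- seq(subject$z[1] - 10, subject$z[9] + 10, by = 4)
  s_probe <- seq(0.05, 0.95, by = 0.1)
  idx <- from_sas(subject, model, s_probe, grid)
  scaled <- landmark_set(3 * subject$z - 40, subject$labels)
  idx2 <- from_sas(scaled, model, s_probe, 3 * grid - 40)
  expect_equal(idx, idx2)
})

test_that("linear baseline is proportional with cranial tie rounding", {
  grid <- seq(0, 100, by = 10)             # 11 slices
  expect_equal(linear_baseline(grid, 0), 1L)
  expect_equal(linear_baseline(grid, 1), 11L)
  expect_equal(linear_baseline(grid, 0.5), 6L)   # middle slice (0-based 5)
  expect_equal(linear_baseline(grid, 0.55), 7L)  # tie 6.5 -> cranial
  expect_error(linear_baseline(c(5, 5), 0.5), "span")
})

test_that("half-level labels match a brute-force nearest-node search", {
  set.seed(9)
  model <- sas_calibrate(replicate(10, random_landmarks(), simplify = FALSE))
  grid <- sas_half_level_grid(model)
  expect_equal(nrow(grid), 17)
  expect_equal(sas_label(model$M[7], model), "T8")
  expect_equal(sas_label((model$M[6] + model$M[7]) / 2, model), "T7-T8")
  for (s in runif(50, -0.02, 1.02)) {
    expect_equal(sas_label(s, model), grid$label[which.min(abs(grid$s - s))])
  }
  expect_match(sas_label(-0.5, model), "T2-sup")
  expect_match(sas_label(1.5, model), "T10-inf")
})
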