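# Synthetic phantom cohort: determinism, ground-truth invariants, the
# planted coupling, and the single-slice companion phantoms.

test_that("identical params and seed reproduce a bit-identical cohort; seeds matter", {
  p <- small_params(n_subjects = 2)
  c1 <- generate_cohort(p, with_companions = FALSE)
  c2 <- generate_cohort(p, with_companions = FALSE)
  expect_identical(c1[[1]]$volume$values, c2[[1]]$volume$values)
  expect_identical(c1[[2]]$truth$sat, c2[[2]]$truth$sat)
  expect_identical(c1[[1]]$landmarks$z, c2[[1]]$landmarks$z)
  p3 <- small_params(n_subjects = 2); p3$seed <- 999
  c3 <- generate_cohort(p3, with_companions = FALSE)
  expect_false(identical(c1[[1]]$volume$values, c3[[1]]$volume$values))
})

test_that("parameter validation names the offending field", {
  expect_error(phantom_params(n_subjects = 1), "n_subjects")
  expect_error(phantom_params(spacing = c(1, 0, 1)), "spacing")
  expect_error(phantom_params(coupling_noise = -0.1), "coupling_noise")
  expect_error(phantom_params(coupling_level = c(SAT = 1.2, VAT = 0.5)),
               "coupling_level")
  expect_error(phantom_params(warp_strength = 0.9), "warp_strength")
})

test_that("degenerate warp and jitter give identical landmarks up to translation/scale", {
  p <- small_params(n_subjects = 4, warp_strength = 0, landmark_jitter = 0)
  co <- generate_cohort(p, with_companions = FALSE)
  norm <- sapply(co, function(s) {
    z <- s$landmarks$z
    (z - z[1]) / (z[length(z)] - z[1])
  })
  for (i in 2:ncol(norm)) expect_equal(norm[, i], norm[, 1], tolerance = 1e-12)
})

test_that("ground-truth masks partition the body and respect the interface", {
  co <- shared_cohort()
  for (s in co[1:3]) {
    tr <- s$truth
    expect_false(any(tr$sat & tr$vat))
    expect_true(all((tr$vat & s$interface_mask) == tr$vat))     # VAT inside cavity
    expect_false(any(tr$sat & s$interface_mask))                # SAT outside cavity
    pairs <- list(tr$sat, tr$vat, s$lung_mask, s$bone_mask, tr$soft)
    for (i in seq_along(pairs)) {
      expect_true(all((pairs[[i]] & tr$body) == pairs[[i]]))    # inside body
      for (j in seq_along(pairs)) if (j > i)
        expect_false(any(pairs[[i]] & pairs[[j]]))              # pairwise disjoint
    }
    # landmark positions strictly monotone along the cranio-caudal axis
    expect_true(all(diff(s$landmarks$z) < 0))
  }
})

test_that("all truth-fat voxels carry fat-window attenuation at default SDs", {
  s <- shared_cohort()[[1]]
  w <- fat_window()
  fatvals <- s$volume$values[s$truth$sat | s$truth$vat]
  expect_gte(mean(fatvals >= w$lower & fatvals <= w$upper), 0.99)
})

test_that("the planted coupling gives near-unity area-volume correlation in truth tables", {
  p <- phantom_params(n_subjects = 40, coupling_noise = 0.02, seed = 31)
  co <- generate_cohort(p, with_companions = FALSE)
  pl <- planted_labels(p)
  for (cp in c("SAT", "VAT")) {
    a_col <- paste0(tolower(cp), "_area_mm2")
    v_name <- paste0(tolower(cp), "_volume_mm3")
    area <- vapply(co, function(s)
      s$truth$level_table[s$truth$level_table$label == pl[[cp]], a_col], 0)
    vol <- vapply(co, function(s) s$truth[[v_name]], 0)
    expect_gte(cor(area, vol), 0.98)
  }
})

test_that("single-slice phantoms honor region, determinism and target geometry", {
  p <- small_params()
  expect_error(generate_single_slice_phantom("pelvis", p), "arg")
  th0 <- generate_single_slice_phantom("thigh", p, seed = 5, vat_area = 0)
  expect_equal(sum(th0$truth$vat), 0)
  a1 <- generate_single_slice_phantom("abdomen", p, seed = 9)
  a2 <- generate_single_slice_phantom("abdomen", p, seed = 9)
  expect_identical(a1$volume$values, a2$volume$values)
  # truth SAT ring area within one voxel layer of the requested analytic area
  pfine <- phantom_params(n_subjects = 2, grid_shape = c(64, 64, 40),
                          spacing = c(4.5, 4.5, 5), seed = 1)
  A <- 6000
  ab <- generate_single_slice_phantom("abdomen", pfine, seed = 2, sat_area = A)
  rx <- 120; ry <- 95
  s_in <- sqrt(1 - A / (pi * rx * ry))
  perim <- function(a, b) pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  layer <- (perim(rx, ry) + perim(s_in * rx, s_in * ry)) * max(pfine$spacing[1:2])
  expect_lt(abs(sum(ab$truth$sat) * prod(pfine$spacing[1:2]) - A), layer)
})

test_that("simulate_cohort_table plants the coupling on the half-level grid", {
  p <- phantom_params(n_subjects = 40, seed = 77)
  tab <- simulate_cohort_table(p)
  expect_s3_class(tab, "cohort_table")
  expect_length(tab$labels, 17)
  pl <- attr(tab, "planted")
  for (cp in c("SAT", "VAT")) {
    r <- cor(tab$areas[[cp]][, pl[[cp]]],
             tab$volumes[[if (cp == "SAT") "SV_C" else "VV_C"]])
    expect_gte(r, 0.98)
  }
})
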