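# Fat segmentation chain: trimming, body/fat/VAT/SAT, marrow correction,
# and the conservation/idempotence/monotonicity invariants.

make_volume <- function(values, spacing = c(1, 1, 5)) image_volume(values, spacing)

test_that("thoracic trimming keeps [base - 5, apex + 15] mm, clipped and rounded outward", {
  nz <- 60; dz <- 5
  vals <- array(0, c(4, 4, nz))
  lung <- array(FALSE, c(4, 4, nz))
  # lung base at z = 50 mm (slice 11), apex at z = 200 mm (slice 41)
  lung[2:3, 2:3, 11:41] <- TRUE
  tr <- trim_thoracic_region(make_volume(vals), lung)
  zpos <- slice_positions(tr$volume)
  expect_equal(min(zpos), 45)    # 50 - 5
  expect_equal(max(zpos), 215)   # 200 + 15
  # ceil(15/5) = 3 extra superior slices, ceil(5/5) = 1 inferior
  expect_equal(tr$slice_range, c(10, 44))
  # lungs touching the acquired top: clipped, no error
  lung2 <- array(FALSE, c(4, 4, nz)); lung2[2:3, 2:3, 11:nz] <- TRUE
  tr2 <- trim_thoracic_region(make_volume(vals), lung2)
  expect_equal(tr2$slice_range[2], nz)
  expect_error(trim_thoracic_region(make_volume(vals), array(FALSE, c(4, 4, nz))),
               "empty")
})

test_that("body segmentation fills interior air cavities but keeps outside air", {
  vals <- array(-1000, c(12, 12, 2))
  vals[3:10, 3:10, ] <- 40                 # body
  vals[5:8, 5:8, ] <- -800                 # internal lung-like cavity
  body <- segment_body(make_volume(vals))
  expect_true(all(body[5:8, 5:8, ]))       # cavity filled
  expect_false(any(body[1:2, , ]))         # outside air untouched
  expect_warning(segment_body(make_volume(array(-1000, c(4, 4, 2)))), "empty")
})

test_that("fat thresholding is closed at both window ends", {
  vals <- array(0, c(2, 3, 1))
  vals[1, 1, 1] <- -40; vals[1, 2, 1] <- -39; vals[1, 3, 1] <- -170
  vals[2, 1, 1] <- -171; vals[2, 2, 1] <- -100; vals[2, 3, 1] <- 40
  body <- array(TRUE, c(2, 3, 1))
  fat <- segment_fat(make_volume(vals), body)
  # column-major order: (-40, -171, -39, -100, -170, +40)
  expect_identical(as.vector(fat), c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(sum(segment_fat(make_volume(array(40, c(4, 4, 2))),
                               array(TRUE, c(4, 4, 2)))), 0)
  expect_error(segment_fat(make_volume(vals), array(TRUE, c(3, 3, 1))),
               "grid mismatch")
})

test_that("VAT opening removes isolated pixels; radius 0 is the raw threshold", {
  vals <- array(0, c(16, 16, 1))
  vals[4:9, 4:9, 1] <- -100                # compact fat blob
  vals[13, 13, 1] <- -100                  # isolated fat pixel
  iface <- array(TRUE, c(16, 16, 1))
  vat1 <- segment_vat(make_volume(vals), iface, opening_radius = 1)
  expect_false(vat1[13, 13, 1])
  expect_true(all(vat1[5:8, 5:8, 1]))
  vat0 <- segment_vat(make_volume(vals), iface, opening_radius = 0)
  expect_identical(vat0, segment_fat(make_volume(vals), iface))
})

test_that("SAT subtraction obeys set arithmetic and conservation", {
  set.seed(21)
  fat <- array(runif(10 * 10 * 4) < 0.5, c(10, 10, 4))
  vat <- fat & array(runif(10 * 10 * 4) < 0.3, c(10, 10, 4))
  sat <- segment_sat(fat, vat)
  expect_equal(sum(sat) + sum(vat & fat), sum(fat))   # conservation
  expect_false(any(sat & vat))
  expect_equal(sum(segment_sat(fat, fat)), 0)
  expect_identical(segment_sat(fat, array(FALSE, dim(fat))), fat)
})

test_that("marrow pseudo-fat inside closed bone is removed; empty bone is a no-op", {
  fat <- array(FALSE, c(16, 16, 1))
  bone <- array(FALSE, c(16, 16, 1))
  bone[6:11, 6:11, 1] <- TRUE
  bone[8:9, 8:9, 1] <- FALSE               # medullary cavity
  fat[8:9, 8:9, 1] <- TRUE                 # pseudo-fat in the cavity
  fat[2, 2, 1] <- TRUE                     # genuine fat far from bone
  out <- remove_marrow_pseudofat(fat, bone)
  expect_false(any(out[8:9, 8:9, 1]))
  expect_true(out[2, 2, 1])
  expect_identical(remove_marrow_pseudofat(fat, array(FALSE, dim(fat))), fat)
})

test_that("phantom segmentation recovers ground truth exactly up to opening effects", {
  # default (fine) grid: the VAT blob spans many pixels so the opening
  # trims only its boundary layer
  s <- generate_subject(phantom_params(seed = 61), "s001", "A", seed = 61)
  tr <- trim_thoracic_region(s$volume, s$lung_mask,
                             masks = list(interface = s$interface_mask,
                                          bone = s$bone_mask))
  seg <- segment_subject(tr$volume, tr$masks$interface, tr$masks$bone)
  keep <- tr$slice_range[1]:tr$slice_range[2]
  tsat <- s$truth$sat[, , keep]; tvat <- s$truth$vat[, , keep]
  # marrow correction restores the exact truth fat count
  expect_equal(sum(seg$fat), sum(tsat) + sum(tvat))
  # body mask matches the generator's body truth
  expect_gte(jaccard_precision(seg$body, s$truth$body[, , keep]), 0.99)
  # compact-blob VAT count within +/-5% of truth (opening trims only boundary)
  expect_lt(abs(sum(seg$vat) - sum(tvat)) / sum(tvat), 0.05)
  expect_false(any(seg$sat & seg$vat))
})

test_that("segment_fat/segment_vat are idempotent and monotone in the window", {
  s <- shared_cohort()[[2]]
  vol <- s$volume
  body <- segment_body(vol)
  fat <- segment_fat(vol, body)
  expect_identical(segment_fat(vol, fat), fat)                  # fixed point
  vat <- segment_vat(vol, s$interface_mask, opening_radius = 1)
  expect_identical(segment_vat(vol, vat, opening_radius = 1), vat)
  wider <- fat_window(-200, -20)
  expect_true(all(fat[segment_fat(vol, body, fat_window()) & !segment_fat(vol, body, wider)] == FALSE))
  expect_true(all((fat & segment_fat(vol, body, wider)) == fat))  # superset
})
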