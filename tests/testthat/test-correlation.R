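# Correlation machinery: PCC/SCC, Jaccard precision, best-slice search
# with independent brute-force confirmation, group comparisons and the
# cohort report.

test_that("pcc matches hand-computed values and rejects degenerate input", {
  expect_equal(pcc(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pcc(1:10, -(1:10)), -1)
  expect_equal(pcc(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pcc(rep(1, 5), 1:5, names = c("flat", "y")), "flat")
  expect_error(pcc(1:3, 1:4), "lengths")
})

test_that("scc is invariant to monotone transforms and handles ties like a rank oracle", {
  set.seed(41)
  x <- rnorm(20)
  expect_equal(scc(x, exp(3 * x)), 1)
  expect_equal(scc(x, -x^3), -1)
  xt <- c(1, 2, 2, 3, 5, 5, 5, 8)
  yt <- c(2, 1, 4, 4, 6, 7, 7, 9)
  # independent oracle: Pearson on explicitly averaged ranks
  avg_rank <- function(v) vapply(v, function(vi)
    mean(which(sort(v) == vi)), numeric(1))
  expect_equal(scc(xt, yt), cor(avg_rank(xt), avg_rank(yt)))
})

test_that("jaccard precision identities hold exactly", {
  m <- array(runif(8 * 8 * 2) < 0.5, c(8, 8, 2))
  m[1, 1, 1] <- TRUE
  expect_equal(jaccard_precision(m, m), 1)
  disj <- array(FALSE, dim(m)); disj[1, 2, 1] <- TRUE
  m2 <- m; m2[1, 2, 1] <- FALSE
  expect_equal(jaccard_precision(m2, disj), 0)
  s2 <- array(FALSE, c(10, 10, 2)); s2[1:10, 1:10, 1] <- TRUE     # 100 voxels
  s1 <- array(FALSE, c(10, 10, 2)); s1[1:5, 1:10, 1] <- TRUE      # nested half
  s2[, , 2] <- FALSE
  expect_equal(jaccard_precision(s1, s2), 0.5)
  expect_equal(jaccard_precision(s1, s2), jaccard_precision(s2, s1))
  expect_error(jaccard_precision(array(FALSE, c(2, 2, 1)),
                                 array(FALSE, c(2, 2, 1))), "empty")
})

test_that("best_slices finds the planted level and agrees with brute force", {
  p <- phantom_params(n_subjects = 40, seed = 55)
  tab <- simulate_cohort_table(p)
  pl <- attr(tab, "planted")
  for (cp in c("SAT", "VAT")) {
    v <- tab$volumes[[if (cp == "SAT") "SV_C" else "VV_C"]]
    A <- tab$areas[[cp]]
    b1 <- best_slices(tab, cp, 1)
    expect_equal(b1$labels, unname(pl[[cp]]))
    expect_equal(b1$rho, cor(A[, pl[[cp]]], v))
    for (k in 2:3) {
      bk <- best_slices(tab, cp, k)
      combos <- combn(ncol(A), k)
      rhos <- apply(combos, 2, function(ix) {
        sm <- rowSums(A[, ix, drop = FALSE])
        if (sd(sm) == 0) NA_real_ else cor(sm, v)
      })
      expect_equal(bk$rho, max(rhos, na.rm = TRUE), tolerance = 1e-12)
      expect_length(bk$labels, k)
      expect_false(anyDuplicated(bk$labels) > 0)
    }
  }
})

test_that("best_slices handles single-label grids and degenerate cohorts", {
  set.seed(56)
  n <- 12
  v <- runif(n, 1, 2)
  a <- v * (1 + rnorm(n, 0, 0.05))
  areas <- list(SAT = matrix(a, n, 1, dimnames = list(NULL, "T8")),
                VAT = matrix(a, n, 1, dimnames = list(NULL, "T8")))
  tab <- cohort_table(data.frame(subject_id = as.character(1:n)),
                      data.frame(SV_C = v, VV_C = v), areas)
  b <- best_slices(tab, "SAT", 1)
  expect_equal(b$labels, "T8")
  expect_equal(b$rho, cor(a, v))
  flat <- areas; flat$SAT[] <- 1; flat$VAT[] <- 1
  tabf <- cohort_table(data.frame(subject_id = as.character(1:n)),
                       data.frame(SV_C = v, VV_C = v), flat)
  expect_error(best_slices(tabf, "SAT", 1), "constant")
})

test_that("group comparison matches its conventions and is symmetric", {
  expect_message(g0 <- group_compare(rep(3, 5), rep(3, 4)), "p = 1")
  expect_equal(g0$p_t, 1); expect_equal(g0$t_statistic, 0)
  set.seed(57)
  a <- rnorm(16, -73, 6); b <- rnorm(16, -66, 5)
  g1 <- group_compare(a, b); g2 <- group_compare(b, a)
  expect_equal(g1$p_t, g2$p_t)
  expect_equal(g1$p_mwu, g2$p_mwu)
  expect_equal(g1$p_t, t.test(a, b, var.equal = TRUE)$p.value)
  gw <- group_compare(a, b, welch = TRUE)
  expect_equal(gw$p_t, t.test(a, b)$p.value)
  expect_error(group_compare(1, c(1, 2)), "at least 2")
})

test_that("correlation report enumerates the full pairing system", {
  tab <- shared_table()
  rep <- correlation_report(tab)
  expect_equal(nrow(rep), 32)
  expect_equal(sum(rep$group == "volume-to-area"), 10)
  expect_equal(sum(rep$group == "area-to-area"), 4)
  expect_equal(sum(rep$group == "hist-volume-to-hist-slice"), 10)
  expect_equal(sum(rep$group == "BMI"), 8)
  expect_true(all(abs(rep$rho_pcc[!rep$missing]) <= 1))
  # affine-function column: exact rho = 1
  tab2 <- tab
  tab2$subjects$SA_A <- 3 * tab2$volumes$SV_C + 0.5
  rep2 <- correlation_report(tab2, with_scc = FALSE)
  expect_equal(rep2$rho_pcc[rep2$pair == "SV_C, SA_A"], 1)
  # missing variable flagged, not fatal
  tab3 <- tab; tab3$subjects$bmi <- NA_real_
  rep3 <- correlation_report(tab3)
  expect_true(all(rep3$missing[rep3$group == "BMI"]))
})

test_that("shuffled-subject null cohorts give correlations near zero", {
  p <- phantom_params(n_subjects = 40, seed = 58)
  tab <- simulate_cohort_table(p)
  v <- tab$volumes$SV_C
  a <- tab$areas$SAT[, attr(tab, "planted")[["SAT"]]]
  set.seed(59)
  null_rho <- replicate(100, cor(sample(a), v))
  expect_lte(mean(abs(null_rho)), 2 / sqrt(40))
})
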