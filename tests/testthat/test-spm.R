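test_that("ensemble band matches the closed-form mean and SD", {
  v <- sin(seq(0, 2 * pi, length.out = 21))
  two <- ensemble_band(rbind(v, -v))
  expect_equal(two$mean$values, rep(0, 21))
  expect_equal(two$sd$values, abs(v) * sqrt(2), tolerance = 1e-12)
  set.seed(61)
  m <- matrix(rnorm(80), 8, 10)
  band <- ensemble_band(m)
  expect_equal(band$mean$values, colMeans(m))
  expect_equal(band$sd$values, apply(m, 2, sd))
  same <- ensemble_band(m[rep(1, 3), ])
  expect_equal(same$sd$values, rep(0, 10))
})

test_that("RMSE report covers cycle and phases and flags unpaired quantities", {
  pct <- seq(0, 100, 1)
  a <- list(x = waveform(pct, rnorm(101), "x", "mm", "gait"))
  ident <- rmse_report(a, a, "gait")
  expect_equal(unlist(ident[1, c("cycle", "stance", "swing")]),
               c(cycle = 0, stance = 0, swing = 0))
  b <- list(x = waveform(pct, a$x$values + 0.7, "x", "mm", "gait"))
  off <- rmse_report(a, b, "gait")
  expect_equal(unname(unlist(off[1, 2:4])), rep(0.7, 3), tolerance = 1e-12)
  set.seed(62)
  cset <- list(x = waveform(pct, rnorm(101), "x", "mm", "gait"))
  r <- rmse_report(a, cset, "gait")
  expect_equal(r$cycle, sqrt(mean((a$x$values - cset$x$values)^2)))
  expect_error(rmse_report(list(y = a$x), a, "gait"), "unpaired")
})

test_that("identical groups produce a null SPM result", {
  set.seed(63)
  g <- gen_smooth_null_curves(8, 101, 15)
  res <- spm_ttest2_1d(g, g)
  expect_equal(res$t_field, rep(0, 101))
  expect_equal(nrow(res$clusters), 0L)
  expect_equal(res$percent_significant, 0)
  # degenerate (zero within-group variance) nodes are floored and flagged
  const <- matrix(1, 4, 101)
  res0 <- spm_ttest2_1d(const, const)
  expect_true(res0$variance_floored)
  expect_equal(res0$t_field, rep(0, 101))
})

test_that("RFT threshold is monotone in smoothness and family size", {
  t1 <- kneebc:::rft_critical_t(20, resels = 100 / 10, alpha = 0.05)
  t2 <- kneebc:::rft_critical_t(20, resels = 100 / 25, alpha = 0.05)
  expect_gt(t1, t2)   # rougher fields need higher thresholds
  a1 <- spm_ttest2_1d(gen_smooth_null_curves(6), gen_smooth_null_curves(6),
                      n_comparisons = 1)
  a4 <- spm_ttest2_1d(gen_smooth_null_curves(6), gen_smooth_null_curves(6),
                      n_comparisons = 4)
  expect_gt(a4$critical_t, a1$critical_t)
  expect_equal(a4$alpha_effective, 0.05 / 4)
})

test_that("percent significant is invariant under affine unit rescaling", {
  set.seed(64)
  A <- gen_smooth_null_curves(10) + 1.5   # genuine offset vs B
  B <- gen_smooth_null_curves(12)
  r1 <- spm_ttest2_1d(A, B)
  r2 <- spm_ttest2_1d(A * 25.4 + 7, B * 25.4 + 7)
  expect_equal(r1$percent_significant, r2$percent_significant)
  expect_equal(r1$t_field, r2$t_field, tolerance = 1e-9)
})

test_that("FWHM estimation recovers the generating smoothness roughly", {
  set.seed(65)
  A <- gen_smooth_null_curves(40, 101, 15)
  B <- gen_smooth_null_curves(40, 101, 15)
  fw <- kneebc:::estimate_fwhm(A, B)
  expect_gt(fw, 10); expect_lt(fw, 22)
})

test_that("RFT and permutation thresholds agree on smooth null data", {
  set.seed(66)
  A <- gen_smooth_null_curves(25, 101, 18)
  B <- gen_smooth_null_curves(25, 101, 18)
  res <- spm_ttest2_1d(A, B)
  perm <- permutation_maxt(A, B, n_perm = 1500, seed = 4L)
  expect_lt(abs(perm$threshold - res$critical_t) / res$critical_t, 0.12)
  perm2 <- permutation_maxt(A, B, n_perm = 1500, seed = 4L)
  expect_identical(perm$max_t, perm2$max_t)   # seeded reproducibility
  expect_warning(permutation_maxt(A, B, n_perm = 50, seed = 1L), "coarse")
})

test_that("family-wise false-positive rate of the SPM test is controlled", {
  set.seed(67)
  n_rep <- 300
  hits <- 0L
  for (i in seq_len(n_rep)) {
    A <- gen_smooth_null_curves(10, 101, 15)
    B <- gen_smooth_null_curves(15, 101, 15)
    res <- spm_ttest2_1d(A, B)
    if (nrow(res$clusters) > 0L) hits <- hits + 1L
  }
  rate <- hits / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(rate, 0.05 + 3 * se)
})
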