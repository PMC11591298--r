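wf_mm <- function(vals, q = "medial_lowpoint_ap") {
  waveform(seq(0, 100, length.out = length(vals)), vals, q, "mm", "gait")
}

test_that("cohort averaging returns identical trials unchanged", {
  w <- wf_mm(sin(seq(0, 2 * pi, length.out = 11)))
  out <- average_cohort(list(S1 = list(w, w), S2 = list(w)),
                        implant_sizes = c(S1 = 60, S2 = 60))
  expect_equal(out$mean$values, w$values, tolerance = 1e-12)
  expect_equal(out$sd$values, rep(0, 11))
})

test_that("cohort averaging is symmetric and matches a hand-computed oracle", {
  v <- c(1, -2, 3)
  sym <- average_cohort(list(A = list(wf_mm(v)), B = list(wf_mm(-v))),
                        implant_sizes = c(A = 60, B = 60))
  expect_equal(sym$mean$values, rep(0, 3))
  # 3 subjects, hand-computed: trial means scaled by mean_size/size, then
  # unweighted subject mean
  trials <- list(
    S1 = list(wf_mm(c(2, 2, 2)), wf_mm(c(4, 4, 4))),   # trial mean 3
    S2 = list(wf_mm(c(6, 6, 6))),
    S3 = list(wf_mm(c(9, 9, 9))))
  sizes <- c(S1 = 50, S2 = 60, S3 = 70)
  out <- average_cohort(trials, implant_sizes = sizes)
  ms <- mean(sizes)
  hand <- mean(c(3 * ms / 50, 6 * ms / 60, 9 * ms / 70))
  expect_equal(out$mean$values, rep(hand, 3), tolerance = 1e-12)
  # rotations are not size-scaled
  deg <- waveform(c(0, 50, 100), c(10, 10, 10), "ie_rotation", "deg", "gait")
  outd <- average_cohort(list(S1 = list(deg)), implant_sizes = c(S1 = 40))
  expect_equal(outd$mean$values, rep(10, 3))
  expect_error(average_cohort(list()), "empty")
})

test_that("body-weight scaling follows the 66 kg mass-ratio rule", {
  wf <- waveform(c(0, 100), c(500, 500), "tf_compression", "N")
  out <- scale_to_body_weight(wf, 76.3)
  expect_equal(out$values, rep(500 * 66 / 76.3, 2), tolerance = 1e-12)
  expect_equal(out$values[1], 432.50, tolerance = 0.005)
  expect_equal(out$units, "N")
  # scaling twice by the square-root ratio equals scaling once
  r <- 66 / 76.3
  two <- scale_to_body_weight(scale_to_body_weight(wf, 66 / sqrt(r)), 66 / sqrt(r))
  expect_equal(two$values, out$values, tolerance = 1e-12)
  expect_error(scale_to_body_weight(wf, 0), "> 0")
})

test_that("sit-stand concatenation places halves and the junction correctly", {
  cst <- waveform(seq(0, 100, 10), rep(7, 11), "flexion", "deg")
  out <- concatenate_sit_stand(cst, cst, n_nodes = 21L)
  expect_equal(out$values, rep(7, 21))
  up <- waveform(seq(0, 100, 10), seq(0, 10, 1), "flexion", "deg")
  dn <- waveform(seq(0, 100, 10), seq(10, 0, -1), "flexion", "deg")
  tri <- concatenate_sit_stand(up, dn, n_nodes = 21L)
  expect_equal(max(tri$values), 10)
  expect_equal(tri$values[11], 10)       # peak at 50%
  expect_equal(tri$values[1], 0)
  # mismatched endpoints a, b meet at (a+b)/2
  wa <- waveform(c(0, 100), c(0, 4), "q", "u")
  wb <- waveform(c(0, 100), c(10, 0), "q", "u")
  mid <- concatenate_sit_stand(wa, wb, n_nodes = 201L)
  expect_equal(mid$values[101], (4 + 10) / 2)
  expect_error(concatenate_sit_stand(wa, waveform(c(0, 100), c(1, 2), "q", "v")),
               "mismatch")
})

test_that("synchronization recovers known circular shifts and is idempotent", {
  n <- 101L
  pct <- seq(0, 100, length.out = n)
  flex <- c(5 + 50 * sin(pi * pct[-n] / 100)^2)
  flex <- c(flex, flex[1])                     # periodic, min at 0%
  shift_by <- function(v, k) { core <- v[-n]; core <- core[(seq_len(n - 1) + k - 1) %% (n - 1) + 1]; c(core, core[1]) }
  sig <- cos(2 * pi * pct / 100)
  k <- 10L
  cyc <- list(list(s = waveform(pct, shift_by(sig, k))))
  fl <- list(waveform(pct, shift_by(flex, k), "flexion", "deg"))
  out <- synchronize(cyc, fl)
  expect_equal(out$shifts, -10L %% 100L)
  # aligned input is unchanged
  cyc0 <- list(list(s = waveform(pct, sig)))
  fl0 <- list(waveform(pct, flex, "flexion", "deg"))
  out0 <- synchronize(cyc0, fl0)
  expect_identical(out0$cycles[[1]]$s$values, sig)
  expect_equal(out0$shifts, 0L)
  expect_warning(synchronize(cyc0, list(waveform(pct, rep(3, n)))), "flat")
})

test_that("phase splitting partitions the cycle at the documented boundaries", {
  wf <- waveform(seq(0, 100, 1), rnorm(101), "ap_translation", "mm", "gait")
  ph <- split_phases(wf)
  expect_named(ph, c("stance", "swing"))
  expect_equal(max(ph$stance$percent_cycle), 60)   # boundary to earlier phase
  expect_equal(min(ph$swing$percent_cycle), 61)
  expect_equal(c(ph$stance$values, ph$swing$values), wf$values)  # partition
  ss <- split_phases(waveform(seq(0, 100, 1), rnorm(101), "x", "mm",
                              "sit_stand"))
  expect_named(ss, c("stand_sit", "sit_stand"))
  expect_equal(max(ss$stand_sit$percent_cycle), 50)
  # whole-cycle RMSE is bracketed by the phase RMSEs
  rmse <- function(v) sqrt(mean(v^2))
  expect_gte(rmse(wf$values), min(rmse(ph$stance$values), rmse(ph$swing$values)))
  expect_lte(rmse(wf$values), max(rmse(ph$stance$values), rmse(ph$swing$values)))
  expect_error(split_phases(wf, activity = "jumping"), "unknown activity")
})

test_that("constant waveforms split into constant phases", {
  wf <- waveform(seq(0, 100, 1), rep(2.5, 101), "x", "mm", "stair_descent")
  ph <- split_phases(wf)
  expect_true(all(ph[[1]]$values == 2.5) && all(ph[[2]]$values == 2.5))
})
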