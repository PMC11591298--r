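make_target <- function(disp_set, d = 49) {
  ap <- disp_set[["A-P"]]$waveform$values
  ie <- disp_set[["I-E"]]$waveform$values
  lp <- ie_ap_to_lowpoints(ie, ap, d)
  df <- data.frame(percent_cycle = disp_set[["A-P"]]$waveform$percent_cycle,
                   medial_ap = lp$medial_ap, lateral_ap = lp$lateral_ap)
  class(df) <- c("lowpoint_series", "data.frame")
  df
}

demo_disp_set <- function(n = 41L) {
  pct <- seq(0, 100, length.out = n)
  assemble_boundary_conditions("implant_specific_displacement", list(
    fluoro_fe = waveform(pct, 20 + 20 * sin(pct / 100 * 2 * pi), "flexion",
                         "deg", "gait"),
    fluoro_ie = waveform(pct, 3 * sin(pct / 100 * 2 * pi), "ie_rotation",
                         "deg", "gait"),
    fluoro_ap = waveform(pct, 2 * cos(pct / 100 * 2 * pi), "ap_translation",
                         "mm", "gait"),
    orthoload_si = waveform(pct, 900 + 500 * sin(pct / 100 * pi),
                            "tf_compression", "N", "gait"),
    mocap_quad = waveform(pct, 300 + 200 * sin(pct / 100 * pi),
                          "quadriceps", "N", "gait")))
}

test_that("low-point RMSE matches its closed-form definition", {
  set.seed(51)
  a <- make_target(demo_disp_set())
  expect_equal(unname(lowpoint_rmse(a, a)), c(0, 0))
  b <- a
  b$medial_ap <- b$medial_ap + 2
  expect_equal(lowpoint_rmse(b, a)[["medial"]], 2)
  cfree <- a
  cfree$medial_ap <- a$medial_ap + rnorm(nrow(a))
  cfree$lateral_ap <- a$lateral_ap + rnorm(nrow(a))
  r <- lowpoint_rmse(cfree, a)
  expect_equal(r[["medial"]], sqrt(mean((cfree$medial_ap - a$medial_ap)^2)))
  expect_equal(r[["lateral"]], sqrt(mean((cfree$lateral_ap - a$lateral_ap)^2)))
  mask <- a$percent_cycle <= 60
  r2 <- lowpoint_rmse(cfree, a, mask)
  expect_equal(r2[["medial"]],
               sqrt(mean((cfree$medial_ap - a$medial_ap)[mask]^2)))
  expect_error(lowpoint_rmse(cfree, a, rep(FALSE, nrow(a))), "empty")
})

test_that("zero fixture compliance converges at the initial replay", {
  knee <- virtual_knee_provider(virtual_knee_params(
    fixture_compliance_ap = 0, fixture_compliance_ie = 0))
  dset <- demo_disp_set()
  res <- derive_load_profiles(make_target(dset), dset, knee)
  expect_true(res$converged)
  expect_equal(res$iterations, 1L)
  expect_lt(max(res$final_rmse), 1e-9)
})

test_that("zero gain freezes the RMSE history after the first replay", {
  knee <- virtual_knee_provider(virtual_knee_params(
    fixture_compliance_ap = 0.08, fixture_compliance_ie = 4e-4))
  dset <- demo_disp_set()
  res <- derive_load_profiles(make_target(dset), dset, knee, gain = 0,
                              tol_mm = 1e-4, max_iter = 6L)
  expect_false(res$converged)
  expect_true(all(abs(res$rmse_history[, 1] - res$rmse_history[1, 1]) < 1e-12))
})

test_that("tuning converges below 2 mm across a 10x compliance range", {
  dset <- demo_disp_set()
  target <- make_target(dset)
  for (c_ap in c(0.004, 0.012, 0.04)) {
    knee <- virtual_knee_provider(virtual_knee_params(
      fixture_compliance_ap = c_ap, fixture_compliance_ie = c_ap / 200))
    res <- derive_load_profiles(target, dset, knee)
    expect_true(res$converged)
    expect_lte(res$iterations, 25L)
    expect_lte(max(res$final_rmse), 2.0)
    # RMSE history non-increasing after the first iteration
    worst <- apply(res$rmse_history, 1, max)
    if (length(worst) > 1) expect_true(all(diff(worst) <= 1e-9))
  }
})

test_that("converged load profiles are a fixed point of the replay", {
  knee <- virtual_knee_provider(virtual_knee_params(
    fixture_compliance_ap = 0.04, fixture_compliance_ie = 2e-4))
  dset <- demo_disp_set()
  target <- make_target(dset)
  res <- derive_load_profiles(target, dset, knee, tol_mm = 0.02)
  expect_true(res$converged)
  replay <- simulate_load_control(res$load_profiles,
                                  virtual_knee_params(
                                    fixture_compliance_ap = 0.04,
                                    fixture_compliance_ie = 2e-4))
  lp <- kneebc:::achieved_lowpoints(replay, 49)
  r <- lowpoint_rmse(lp, target)
  expect_lt(max(abs(r - res$final_rmse)), 0.05)
})
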