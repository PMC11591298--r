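test_that("expected bead loads follow the lever-arm arithmetic", {
  expect_equal(unname(expected_loads(c(0, 0))), c(1000, 0, 0))
  expect_equal(unname(expected_loads(c(10, 0))), c(1000, 0, 10000))
  a <- expected_loads(c(12, -7), force = 500)
  b <- expected_loads(c(-12, 7), force = 500)
  expect_equal(unname(a[2:3]), -unname(b[2:3]))   # antisymmetric beads
  expect_error(expected_loads(c(1, 1), force = 0), "> 0")
})

test_that("noiseless bead sweep identifies the true calibration matrix", {
  M <- test_cal_matrix()
  g <- gen_tray_readings(M, noise_sd = 0)
  fit <- solve_calibration(g$readings, g$known_loads)
  expect_lt(max(abs(fit$matrix - M$matrix)) / max(abs(M$matrix)), 1e-9)
  expect_lt(max(fit$residual_rms), 1e-9)
  # calibrated outputs reproduce the expected loads exactly
  out <- apply_calibration(fit, g$readings)
  expect_equal(unname(out), unname(g$known_loads), tolerance = 1e-9)
})

test_that("noiseless recovery holds for random full-row-rank matrices", {
  set.seed(31)
  for (i in 1:10) {
    M <- calibration_matrix(matrix(rnorm(12, sd = 5), 3, 4))
    g <- gen_tray_readings(M, noise_sd = 0)
    fit <- solve_calibration(g$readings, g$known_loads)
    expect_lt(max(abs(fit$matrix - M$matrix)) / max(abs(M$matrix)), 1e-9)
  }
})

test_that("exactly determined and noisy solves match the pseudo-inverse oracle", {
  M <- test_cal_matrix()
  beads4 <- data.frame(bead_id = paste0("B", 1:4),
                       x = c(0, 20, -15, 5), y = c(0, 5, 10, -20))
  g4 <- gen_tray_readings(M, beads = beads4, noise_sd = 0)
  fit4 <- solve_calibration(g4$readings, g4$known_loads)
  expect_lt(max(fit4$residual_rms), 1e-9)
  gn <- gen_tray_readings(M, noise_sd = 0.5, seed = 3L)
  fit <- solve_calibration(gn$readings, gn$known_loads)
  s <- svd(gn$readings)
  pinv <- s$v %*% (1 / s$d * t(s$u))
  oracle <- unname(t(pinv %*% gn$known_loads))
  expect_equal(fit$matrix, oracle, tolerance = 1e-10)
  # reproducible noise under a fixed seed
  gn2 <- gen_tray_readings(M, noise_sd = 0.5, seed = 3L)
  expect_identical(gn$readings, gn2$readings)
})

test_that("rank-deficient channel data are rejected with a named deficiency", {
  readings <- cbind(rep(1, 6), rep(2, 6), rep(3, 6), rep(4, 6))
  loads <- matrix(rnorm(18), 6, 3)
  expect_error(solve_calibration(readings, loads), "span only 1 dimension")
})

test_that("calibration application is linear", {
  M <- test_cal_matrix()
  r1 <- c(10, 20, 30, 40); r2 <- c(-5, 3, 7, 1)
  expect_equal(apply_calibration(M, r1 + r2),
               apply_calibration(M, r1) + apply_calibration(M, r2),
               tolerance = 1e-12)
  expect_equal(unname(apply_calibration(M, rep(0, 4))), rep(0, 3))
  expect_equal(unname(apply_calibration(M, r1)), drop(M$matrix %*% r1))
  expect_error(apply_calibration(M, c(1, 2, 3)), "4 channel")
})
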