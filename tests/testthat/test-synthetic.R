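test_that("zero-noise low-point trajectories equal the mean shape", {
  act <- gait_act(51L)
  subs <- demo_subjects(5)
  trajs <- gen_lowpoint_trajectories(act, subs, sd_medial = 0, sd_lateral = 0)
  shape <- default_lowpoint_shape("gait")
  pct <- trajs[[1]]$percent_cycle
  truth_med <- kneebc:::fourier_eval(shape$medial, pct)
  for (tr in trajs) {
    expect_equal(tr$medial_ap, truth_med, tolerance = 1e-12)
    expect_equal(tr$medial_ap, trajs[[1]]$medial_ap)
  }
})

test_that("between-subject SD converges to the requested 1.2/1.9 mm", {
  act <- gait_act(51L)
  subs <- demo_subjects(200)
  trajs <- gen_lowpoint_trajectories(act, subs, sd_medial = 1.2,
                                     sd_lateral = 1.9)
  med <- do.call(rbind, lapply(trajs, `[[`, "medial_ap"))
  lat <- do.call(rbind, lapply(trajs, `[[`, "lateral_ap"))
  sd_med <- apply(med, 2, sd)
  sd_lat <- apply(lat, 2, sd)
  expect_lt(max(abs(sd_med - 1.2) / 1.2), 0.15)
  expect_lt(max(abs(sd_lat - 1.9) / 1.9), 0.15)
})

test_that("generators are bit-identical under a fixed seed", {
  act <- gait_act(31L)
  subs <- demo_subjects(3, seed = 9L)
  expect_identical(gen_lowpoint_trajectories(act, subs),
                   gen_lowpoint_trajectories(act, subs))
  M <- test_cal_matrix()
  expect_identical(gen_tray_readings(M, noise_sd = 1, seed = 5L),
                   gen_tray_readings(M, noise_sd = 1, seed = 5L))
  fid <- matrix(rnorm(12), 4, 3)
  poses <- list(random_pose(), random_pose())
  expect_identical(gen_marker_data(poses, fid, noise_sd = 0.1, seed = 2L),
                   gen_marker_data(poses, fid, noise_sd = 0.1, seed = 2L))
})

test_that("non-finite shape parameters are rejected", {
  act <- gait_act(21L)
  bad <- default_lowpoint_shape("gait")
  bad$medial$a[1] <- NaN
  expect_error(gen_lowpoint_trajectories(act, demo_subjects(2),
                                         mean_shape_params = bad),
               "non-finite")
  expect_error(gen_lowpoint_trajectories(act, demo_subjects(2),
                                         sd_medial = -1), ">= 0")
})

test_that("peak-constructed load waveforms honor their control points", {
  act <- gait_act()
  single <- gen_load_waveforms(act, peaks = list(
    quadriceps = data.frame(percent = 50, value = 1000)))$quadriceps
  expect_equal(max(single$values), 1000)
  expect_equal(single$percent_cycle[which.max(single$values)], 50)
  zero <- gen_load_waveforms(act, peaks = list(
    quadriceps = data.frame(percent = c(20, 80), value = c(0, 0))))$quadriceps
  expect_equal(zero$values, rep(0, 101))
  defaults <- gen_load_waveforms(act)
  expect_equal(max(defaults$quadriceps$values), 651)
  expect_error(gen_load_waveforms(act, peaks = list(
    q = data.frame(percent = 120, value = 1))), "\\[0, 100\\]")
})

test_that("marker data compose pose and noise as specified", {
  fid <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(3, 4, 5))
  ident <- gen_marker_data(list(pose()), fid, noise_sd = 0)
  expect_equal(ident[[1]], fid)
  truth <- pose(rot_z(30), c(1, -2, 3))
  obs <- gen_marker_data(list(truth), fid, noise_sd = 0)[[1]]
  fit <- kabsch_fit(fid, obs)
  expect_lt(rot_angle_deg(fit$pose$rotation, truth$rotation), 1e-7)
  line <- cbind(1:4, 1:4, 1:4)
  expect_error(gen_marker_data(list(pose()), line, 0), "collinear")
})

test_that("marker-noise propagation matches least-squares theory", {
  set.seed(33)
  fid <- rbind(c(0, 0, 0), c(40, 0, 0), c(0, 40, 0), c(0, 0, 40),
               c(20, 20, 0), c(0, 20, 20))
  n <- nrow(fid)
  sigma <- 0.1
  poses <- replicate(400, random_pose(20), simplify = FALSE)
  obs <- gen_marker_data(poses, fid, noise_sd = sigma, seed = 8L)
  ss <- vapply(seq_along(poses), function(i)
    n * kabsch_fit(fid, obs[[i]])$rms^2, numeric(1))
  # E[residual sum of squares] = sigma^2 (3n - 6) for a rigid fit
  expect_equal(mean(ss), sigma^2 * (3 * n - 6), tolerance = 0.1)
})
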