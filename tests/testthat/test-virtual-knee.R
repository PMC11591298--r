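# Minimal single-activity displacement profile set on a coarse grid.
make_disp_set <- function(n = 11L, ap_cmd = NULL, ie_cmd = NULL,
                          flex = NULL, si = 1000, quad = 0) {
  pct <- seq(0, 100, length.out = n)
  const <- function(v, q, u) waveform(pct, rep_len(v, n), q, u, "gait")
  assemble_boundary_conditions("implant_specific_displacement", list(
    fluoro_fe = if (is.null(flex)) const(0, "flexion", "deg")
                else waveform(pct, flex, "flexion", "deg", "gait"),
    fluoro_ie = if (is.null(ie_cmd)) const(0, "ie_rotation", "deg")
                else waveform(pct, ie_cmd, "ie_rotation", "deg", "gait"),
    fluoro_ap = if (is.null(ap_cmd)) const(0, "ap_translation", "mm")
                else waveform(pct, ap_cmd, "ap_translation", "mm", "gait"),
    orthoload_si = const(si, "tf_compression", "N"),
    mocap_quad = const(quad, "quadriceps", "N")))
}

to_load_set <- function(disp_set, f_ap, t_ie) {
  grid <- disp_set[["F-E"]]$waveform$percent_cycle
  assemble_boundary_conditions("implant_specific_load", list(
    fluoro_fe = disp_set[["F-E"]]$waveform,
    orthoload_si = disp_set[["S-I"]]$waveform,
    mocap_quad = disp_set[["Quad"]]$waveform,
    derived_ap = waveform(grid, rep_len(f_ap, length(grid)), "ap_force", "N"),
    derived_ie = waveform(grid, rep_len(t_ie, length(grid)), "ie_torque", "Nmm")))
}

test_that("rigid fixtures make achieved kinematics equal commanded", {
  params <- virtual_knee_params(fixture_compliance_ap = 0,
                                fixture_compliance_ie = 0)
  set <- make_disp_set(ap_cmd = seq(-3, 3, length.out = 11),
                       ie_cmd = seq(-2, 2, length.out = 11))
  sim <- simulate_displacement_control(set, params)
  expect_equal(sim$achieved$anterior_posterior,
               set[["A-P"]]$waveform$values, tolerance = 1e-12)
  expect_equal(sim$achieved$internal_external,
               set[["I-E"]]$waveform$values, tolerance = 1e-12)
})

test_that("recorded actuator load follows Hooke's law about the dwell", {
  params <- virtual_knee_params(fixture_compliance_ap = 0,
                                fixture_compliance_ie = 0,
                                dwell_ap_of_flexion = c(0, 0))
  x <- 2.5
  set <- make_disp_set(ap_cmd = rep(x, 11), si = 1000, quad = 0)
  sim <- simulate_displacement_control(set, params)
  k <- params$baseline_ap_stiffness + params$ap_stiffness_per_compression * 1
  expect_equal(sim$recorded$ap_force$values, rep(k * x, 11),
               tolerance = 1e-12)
  # zero offset at dwell, zero quad -> zero recorded transverse loads
  sim0 <- simulate_displacement_control(make_disp_set(), params)
  expect_equal(sim0$recorded$ap_force$values, rep(0, 11))
  expect_equal(sim0$recorded$ie_torque$values, rep(0, 11))
})

test_that("load control solves the linear equilibrium closed form", {
  params <- virtual_knee_params(dwell_ap_of_flexion = c(0, 0))
  disp <- make_disp_set(si = 1500, quad = 0)
  f <- 80; t <- 3000
  sim <- simulate_load_control(to_load_set(disp, f, t), params)
  k_ap <- params$baseline_ap_stiffness +
    params$ap_stiffness_per_compression * 1.5
  k_ie <- params$baseline_ie_stiffness +
    params$ie_stiffness_per_compression * 1.5
  expect_equal(sim$achieved$anterior_posterior, rep(f / k_ap, 11),
               tolerance = 1e-12)
  expect_equal(sim$achieved$internal_external, rep(t / k_ie, 11),
               tolerance = 1e-12)
  expect_lt(sim$max_equilibrium_residual, 1e-6)
  # zero applied loads, zero quad -> dwell kinematics
  sim0 <- simulate_load_control(to_load_set(disp, 0, 0), params)
  expect_equal(sim0$achieved$anterior_posterior, rep(0, 11))
})

test_that("articular compression includes the extensor contribution", {
  params <- virtual_knee_params()
  flex <- seq(0, 60, length.out = 11)
  disp <- make_disp_set(flex = flex, si = 800, quad = 400)
  sim <- simulate_load_control(to_load_set(disp, 0, 0), params)
  expect_true(all(sim$states$compression >= sim$states$applied_si))
  # articular A-P stiffness strictly increases with compression
  expect_true(all(diff(order(sim$states$compression)) ==
                    diff(order(sim$states$k_ap))))
  k_of_c <- sim$states$k_ap[order(sim$states$compression)]
  expect_true(all(diff(k_of_c) >= 0))
})

test_that("patellofemoral response is zero at zero quad and homogeneous", {
  params <- virtual_knee_params()
  expect_equal(pf_response(45, 0, params)$pf_resultant, 0)
  r1 <- pf_response(45, 300, params)
  r2 <- pf_response(45, 600, params)
  expect_equal(r2$pf_resultant, 2 * r1$pf_resultant, tolerance = 1e-12)
  # two-force-member closed form at one flexion angle
  wrap <- params$pf_wrap_coefs[1] + params$pf_wrap_coefs[2] * 45 * pi / 180
  expect_equal(r1$pf_resultant, 2 * 300 * sin(wrap / 2), tolerance = 1e-12)
  expect_error(pf_response(45, -10, params), ">= 0")
})

test_that("displacement control then load-control replay is a fixed point at zero compliance", {
  params <- virtual_knee_params(fixture_compliance_ap = 0,
                                fixture_compliance_ie = 0)
  set <- make_disp_set(ap_cmd = sin(seq(0, 2 * pi, length.out = 11)) * 3,
                       ie_cmd = cos(seq(0, 2 * pi, length.out = 11)) * 2,
                       flex = seq(0, 60, length.out = 11),
                       si = 1200, quad = 300)
  rec <- simulate_displacement_control(set, params)
  lset <- to_load_set(set, rec$recorded$ap_force$values,
                      rec$recorded$ie_torque$values)
  replay <- simulate_load_control(lset, params)
  expect_equal(replay$achieved$anterior_posterior,
               set[["A-P"]]$waveform$values, tolerance = 1e-10)
  expect_equal(replay$achieved$internal_external,
               set[["I-E"]]$waveform$values, tolerance = 1e-10)
})
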