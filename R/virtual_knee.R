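#' Parameters of the quasi-static virtual knee surrogate
#'
#' The virtual knee is an entirely synthetic quasi-static stand-in for an
#' implanted knee mounted in a 6-DoF joint simulator with a quadriceps
#' actuator. It exists so that profile tuning and kinematic evaluation
#' can run at desk scale; it is not a model of any specific implant. The
#' articulation provides a restoring force in A-P translation and a
#' restoring torque in I-E rotation, both linear about a
#' flexion-dependent dwell line, with stiffnesses that increase linearly
#' with the tibiofemoral compression carried by the insert (low
#' compression means low articular constraint). The extensor mechanism
#' adds a flexion-dependent fraction of the quadriceps force to the
#' articular compression and loads the patellofemoral joint through a
#' tendon wrap angle. Fixture compliance acts as a series spring between
#' the actuator and the implant, so displacement-controlled commands are
#' attained only approximately when the articulation pushes back.
#'
#' @param ap_stiffness_per_compression articular A-P stiffness gain,
#'   N/mm per kN of compression.
#' @param ie_stiffness_per_compression articular I-E stiffness gain,
#'   Nmm/deg per kN of compression.
#' @param baseline_ap_stiffness N/mm at zero compression, `> 0`.
#' @param baseline_ie_stiffness Nmm/deg at zero compression, `> 0`.
#' @param fixture_compliance_ap mm/N, `>= 0`.
#' @param fixture_compliance_ie deg/Nmm, `>= 0`.
#' @param dwell_ap_of_flexion polynomial coefficients (ascending, mm,
#'   mm/deg, ...) of the A-P dwell point vs flexion.
#' @param quad_to_compression_gain_of_flexion polynomial coefficients
#'   (ascending, per deg) of the extensor-to-compression gain vs flexion.
#' @param extensor_moment_arm_of_flexion polynomial coefficients
#'   (ascending, mm) of the extensor moment arm vs flexion.
#' @param pf_wrap_coefs `c(offset_rad, rad_per_rad_flexion)` extensor
#'   wrap angle vs flexion for the patellofemoral resultant.
#' @return an object of class `"virtual_knee_params"`.
#' @export
virtual_knee_params <- function(ap_stiffness_per_compression = 30,
                                ie_stiffness_per_compression = 1500,
                                baseline_ap_stiffness = 15,
                                baseline_ie_stiffness = 400,
                                fixture_compliance_ap = 0.004,
                                fixture_compliance_ie = 2e-5,
                                dwell_ap_of_flexion = c(0, -0.04),
                                quad_to_compression_gain_of_flexion = c(0.30, 0.004),
                                extensor_moment_arm_of_flexion = c(45, -0.10),
                                pf_wrap_coefs = c(0.15, 1.0)) {
  p <- list(ap_stiffness_per_compression = ap_stiffness_per_compression,
            ie_stiffness_per_compression = ie_stiffness_per_compression,
            baseline_ap_stiffness = baseline_ap_stiffness,
            baseline_ie_stiffness = baseline_ie_stiffness,
            fixture_compliance_ap = fixture_compliance_ap,
            fixture_compliance_ie = fixture_compliance_ie,
            dwell_ap_of_flexion = dwell_ap_of_flexion,
            quad_to_compression_gain_of_flexion = quad_to_compression_gain_of_flexion,
            extensor_moment_arm_of_flexion = extensor_moment_arm_of_flexion,
            pf_wrap_coefs = pf_wrap_coefs)
  if (baseline_ap_stiffness <= 0 || baseline_ie_stiffness <= 0 ||
      ap_stiffness_per_compression < 0 || ie_stiffness_per_compression < 0)
    stop("stiffness parameters must be positive")
  if (fixture_compliance_ap < 0 || fixture_compliance_ie < 0)
    stop("fixture compliances must be >= 0")
  structure(p, class = "virtual_knee_params")
}

polyval_asc <- function(coefs, x) {
  out <- 0
  for (k in rev(seq_along(coefs))) out <- out * x + coefs[k]
  out
}

# Per-node articular state shared by both control modes.
vk_node_state <- function(params, flexion, si_load, quad_force) {
  gain <- pmax(0, polyval_asc(params$quad_to_compression_gain_of_flexion,
                              flexion))
  compression <- si_load + gain * quad_force
  list(
    compression = compression,
    dwell_ap = polyval_asc(params$dwell_ap_of_flexion, flexion),
    k_ap = params$baseline_ap_stiffness +
      params$ap_stiffness_per_compression * compression / 1000,
    k_ie = params$baseline_ie_stiffness +
      params$ie_stiffness_per_compression * compression / 1000)
}

#' Patellofemoral response to quadriceps loading
#'
#' Two-force-member tendon wrap: the patellofemoral resultant is
#' `2 * quad * sin(wrap / 2)` with a flexion-dependent wrap angle, and
#' the extensor mechanism adds `gain(flexion) * quad` to the articular
#' tibiofemoral compression. The resultant is zero at zero quadriceps
#' force and homogeneous (linear) in it.
#'
#' @param flexion knee flexion, deg (vectorized).
#' @param quad_force quadriceps force, N, `>= 0`.
#' @param params a [virtual_knee_params()].
#' @return list with `pf_resultant` (N) and `tf_compression_increment`
#'   (N).
#' @export
pf_response <- function(flexion, quad_force, params = virtual_knee_params()) {
  if (any(quad_force < 0)) stop("quad_force must be >= 0")
  wrap <- params$pf_wrap_coefs[1] + params$pf_wrap_coefs[2] * flexion * pi / 180
  gain <- pmax(0, polyval_asc(params$quad_to_compression_gain_of_flexion,
                              flexion))
  list(pf_resultant = 2 * quad_force * sin(pmax(0, wrap) / 2),
       tf_compression_increment = gain * quad_force)
}

bc_values <- function(profiles, dof, mode = NULL) {
  p <- profiles[[dof]]
  if (is.null(p)) stop("profile set is missing DoF ", dof)
  if (!is.null(mode) && p$control_mode != mode)
    stop(sprintf("DoF %s must be in %s control for this simulation", dof, mode))
  p$waveform$values
}

#' Simulate the virtual knee under displacement control
#'
#' F-E, A-P, and I-E follow displacement commands; S-I compression and
#' the quadriceps are in load control. Per node, the actuator load
#' required to hold the commanded transverse-plane kinematics against
#' the articular restoring action is recorded; with nonzero fixture
#' compliance the implant attains only part of the commanded offset
#' (series-spring equilibrium), so achieved kinematics differ from
#' commanded.
#'
#' @param profiles a `"bc_profile_set"` with F-E, A-P, I-E in
#'   displacement mode (variant `"implant_specific_displacement"`).
#' @param params a [virtual_knee_params()].
#' @return list with `recorded` (A-P force and I-E torque [waveform()]s),
#'   `achieved` (data frame of achieved F-E, A-P, I-E per node),
#'   `states` (per-node articular quantities), and
#'   `max_equilibrium_residual`.
#' @export
simulate_displacement_control <- function(profiles, params = virtual_knee_params()) {
  stopifnot(inherits(profiles, "bc_profile_set"),
            inherits(params, "virtual_knee_params"))
  fe <- bc_values(profiles, "F-E", "displacement")
  ap_cmd <- bc_values(profiles, "A-P", "displacement")
  ie_cmd <- bc_values(profiles, "I-E", "displacement")
  si <- bc_values(profiles, "S-I", "load")
  quad <- bc_values(profiles, "Quad", "load")
  grid <- profiles[["F-E"]]$waveform$percent_cycle
  st <- vk_node_state(params, fe, si, quad)
  # series springs: actuator commands x_c; implant attains x_a with
  # k_fixture (x_c - x_a) = k_articular (x_a - dwell); recorded load is
  # the force in the chain.
  f_ap <- (ap_cmd - st$dwell_ap) /
    (1 / st$k_ap + params$fixture_compliance_ap)
  x_ap <- st$dwell_ap + f_ap / st$k_ap
  t_ie <- ie_cmd / (1 / st$k_ie + params$fixture_compliance_ie)
  x_ie <- t_ie / st$k_ie
  resid <- pmax(abs(f_ap - st$k_ap * (x_ap - st$dwell_ap)),
                abs(t_ie - st$k_ie * x_ie))
  char_load <- pmax(abs(f_ap), abs(t_ie), 1)
  pf <- pf_response(fe, quad, params)
  act <- profiles[["F-E"]]$waveform$activity
  list(
    recorded = list(
      ap_force = waveform(grid, f_ap, "ap_force", "N", act),
      ie_torque = waveform(grid, t_ie, "ie_torque", "Nmm", act)),
    achieved = data.frame(percent_cycle = grid, flexion = fe,
                          anterior_posterior = x_ap,
                          internal_external = x_ie),
    states = data.frame(percent_cycle = grid,
                        compression = st$compression,
                        pf_resultant = pf$pf_resultant,
                        k_ap = st$k_ap, k_ie = st$k_ie,
                        dwell_ap = st$dwell_ap),
    max_equilibrium_residual = max(resid / char_load))
}

#' Simulate the virtual knee under load control
#'
#' F-E follows its displacement command; A-P force and I-E torque are
#' applied as loads and the per-node quasi-static equilibrium is solved
#' for the transverse-plane displacements. The articular compression
#' includes the extensor-mechanism contribution, so the compression felt
#' by the insert exceeds the applied S-I load whenever the quadriceps is
#' tensioned.
#'
#' @param profiles a `"bc_profile_set"` with A-P and I-E in load mode
#'   (variant `"implant_specific_load"` or `"cams"`).
#' @param params a [virtual_knee_params()].
#' @return list with `achieved` (data frame of F-E, A-P, I-E per node),
#'   `states` (articular compression, PF resultant, stiffnesses), and
#'   `max_equilibrium_residual`.
#' @export
simulate_load_control <- function(profiles, params = virtual_knee_params()) {
  stopifnot(inherits(profiles, "bc_profile_set"),
            inherits(params, "virtual_knee_params"))
  fe <- bc_values(profiles, "F-E", "displacement")
  f_ap <- bc_values(profiles, "A-P", "load")
  t_ie <- bc_values(profiles, "I-E", "load")
  si <- bc_values(profiles, "S-I", "load")
  quad <- bc_values(profiles, "Quad", "load")
  grid <- profiles[["F-E"]]$waveform$percent_cycle
  st <- vk_node_state(params, fe, si, quad)
  x_ap <- st$dwell_ap + f_ap / st$k_ap
  x_ie <- t_ie / st$k_ie
  resid <- pmax(abs(f_ap - st$k_ap * (x_ap - st$dwell_ap)),
                abs(t_ie - st$k_ie * x_ie))
  char_load <- pmax(abs(f_ap), abs(t_ie), 1)
  pf <- pf_response(fe, quad, params)
  list(
    achieved = data.frame(percent_cycle = grid, flexion = fe,
                          anterior_posterior = x_ap,
                          internal_external = x_ie),
    states = data.frame(percent_cycle = grid,
                        compression = st$compression,
                        applied_si = si,
                        pf_resultant = pf$pf_resultant,
                        k_ap = st$k_ap, k_ie = st$k_ie,
                        dwell_ap = st$dwell_ap),
    max_equilibrium_residual = max(resid / char_load))
}

#' A knee response provider backed by the virtual knee
#'
#' Wraps [simulate_displacement_control()] and
#' [simulate_load_control()] into the provider interface consumed by
#' [derive_load_profiles()], so the tuning loop can run against any
#' object with the same two functions.
#'
#' @param params a [virtual_knee_params()].
#' @return list with functions `displacement_control(profiles)` and
#'   `load_control(profiles)`.
#' @export
virtual_knee_provider <- function(params = virtual_knee_params()) {
  list(displacement_control = function(profiles)
         simulate_displacement_control(profiles, params),
       load_control = function(profiles)
         simulate_load_control(profiles, params))
}
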