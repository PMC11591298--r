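# Shared fixture builders (all generated in code; no data files).

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_pose <- function(trans_scale = 50) {
  pose(random_rotation(), rnorm(3, 0, trans_scale))
}

# JCS states away from gimbal lock
random_jcs <- function() {
  jcs_state(flexion_extension = runif(1, -30, 120),
            adduction_abduction = runif(1, -45, 45),
            internal_external = runif(1, -40, 40),
            medial_lateral = rnorm(1, 0, 10),
            anterior_posterior = rnorm(1, 0, 10),
            superior_inferior = rnorm(1, -40, 10))
}

jcs_vec <- function(j) unlist(j, use.names = FALSE)

# Geodesic angle (deg) between two rotation matrices, clamped for
# floating-point safety.
rot_angle_deg <- function(Ra, Rb) {
  c <- (sum(diag(crossprod(Ra, Rb))) - 1) / 2
  acos(max(-1, min(1, c))) * 180 / pi
}

# Known full-row-rank tray calibration matrix: equal force sharing plus
# antisymmetric moment arms.
test_cal_matrix <- function() {
  calibration_matrix(matrix(c(0.25, 0.25, 0.25, 0.25,
                              6, -6, 6, -6,
                              7, 7, -7, -7), 3, 4, byrow = TRUE))
}

gait_act <- function(n = 101L) activity_spec("gait", n)

demo_subjects <- function(n, seed = 1L) {
  lapply(seq_len(n), function(i)
    subject_spec(sprintf("S%02d", i), body_mass = 60 + i,
                 implant_ap_size = 58 + i %% 5, seed = seed))
}

# Small, fast pipeline configuration for tests
small_run_config <- function(seed = 1L) {
  cfg <- default_run_config(seed)
  cfg$activities <- "gait"
  cfg$cohort$n_subjects <- 6L
  cfg$cohort$n_trials <- 2L
  cfg$specimens$n_specimens <- 4L
  cfg$report <- FALSE
  cfg
}
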