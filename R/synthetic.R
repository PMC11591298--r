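#' Describe a synthetic study subject
#'
#' Carries the per-subject scaling factors used during cohort averaging:
#' body mass (for body-weight normalization of loads) and the femoral
#' implant anterior-posterior dimension (for implant-size normalization
#' of translations).
#'
#' @param subject_id label.
#' @param body_mass kg, `> 0`.
#' @param implant_ap_size femoral A-P dimension, mm, `> 0`.
#' @param seed per-subject RNG substream seed.
#' @return an object of class `"subject_spec"`.
#' @export
subject_spec <- function(subject_id, body_mass = 66, implant_ap_size = 62,
                         seed = 1L) {
  if (!is.finite(body_mass) || body_mass <= 0) stop("body_mass must be > 0")
  if (!is.finite(implant_ap_size) || implant_ap_size <= 0)
    stop("implant_ap_size must be > 0")
  structure(list(subject_id = as.character(subject_id),
                 body_mass = body_mass, implant_ap_size = implant_ap_size,
                 seed = as.integer(seed)),
            class = "subject_spec")
}

#' Describe an activity cycle
#'
#' @param activity one of `"gait"`, `"stair_descent"`, `"sit_stand"`.
#' @param n_samples nodes on the 0-100% cycle grid (default 101), `>= 3`.
#' @param stance_fraction heel strike to toe-off fraction of the cycle
#'   for gait-like activities (default 0.60); the sit-stand cycle splits
#'   at 0.50 between the stand-to-sit and sit-to-stand halves.
#' @return an object of class `"activity_spec"`.
#' @export
activity_spec <- function(activity = c("gait", "stair_descent", "sit_stand"),
                          n_samples = 101L, stance_fraction = NULL) {
  activity <- match.arg(activity)
  if (is.null(stance_fraction))
    stance_fraction <- if (activity == "sit_stand") 0.5 else 0.6
  if (n_samples < 3L) stop("n_samples must be >= 3")
  if (!is.finite(stance_fraction) || stance_fraction <= 0 || stance_fraction >= 1)
    stop("stance_fraction must be in (0, 1)")
  structure(list(activity = activity, n_samples = as.integer(n_samples),
                 stance_fraction = stance_fraction),
            class = "activity_spec")
}

cycle_grid <- function(activity) seq(0, 100, length.out = activity$n_samples)

# Evaluate a truncated Fourier series on the percent-cycle grid.
# coefs: list(a0 = ..., a = c(...), b = c(...)).
fourier_eval <- function(coefs, percent) {
  th <- percent / 100 * 2 * pi
  out <- rep(coefs$a0 %||% 0, length(percent))
  a <- coefs$a %||% numeric(0)
  b <- coefs$b %||% numeric(0)
  for (k in seq_along(a)) out <- out + a[k] * cos(k * th)
  for (k in seq_along(b)) out <- out + b[k] * sin(k * th)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Default mean condylar low-point shapes
#'
#' Low-order Fourier coefficients (mm) for the mean medial and lateral
#' femoral low-point A-P trajectories of each activity. The shapes are
#' synthetic but carry the morphology the analysis assumes: small medial
#' excursion with a late-cycle anterior oscillation for gait, moderate
#' excursions for stair descent, and a flexion-coupled anterior medial /
#' posteriorly offset lateral pattern for sit-stand.
#'
#' @param activity activity name.
#' @return list with `medial` and `lateral` coefficient sets.
#' @export
default_lowpoint_shape <- function(activity = c("gait", "stair_descent",
                                                "sit_stand")) {
  activity <- match.arg(activity)
  switch(activity,
    gait = list(
      medial = list(a0 = -0.3, a = c(0.45, -0.45), b = c(0.6, 0.35)),
      lateral = list(a0 = -1.8, a = c(0.9, -0.8), b = c(1.2, 0.5))),
    stair_descent = list(
      medial = list(a0 = -0.8, a = c(1.6, -0.9), b = c(2.0, 0.5)),
      lateral = list(a0 = -2.0, a = c(1.2, -0.7), b = c(1.6, 0.4))),
    sit_stand = list(
      medial = list(a0 = 0.4, a = c(-1.0, 0.15), b = c(0.25, 0)),
      lateral = list(a0 = -4.0, a = c(0.8, -0.2), b = c(0.3, 0))))
}

#' Generate per-subject condylar low-point trajectories
#'
#' Each subject's medial and lateral low-point A-P trajectories are the
#' activity mean shape plus a smooth periodic subject-specific deviation
#' (random offset plus three random Fourier harmonics) whose pointwise
#' standard deviation equals the requested between-subject SD. Defaults
#' of 1.2 mm (medial) and 1.9 mm (lateral) reflect the consistently
#' tighter medial-condyle variability seen in fluoroscopic TKA cohorts.
#'
#' @param activity an [activity_spec()].
#' @param subjects list of [subject_spec()]s.
#' @param mean_shape_params coefficient set as in
#'   [default_lowpoint_shape()].
#' @param sd_medial,sd_lateral between-subject pointwise SD in mm, `>= 0`.
#' @param intercondylar_distance mm, used for the constant
#'   medial-lateral low-point offsets.
#' @param n_harmonics harmonics in the subject deviation (default 3).
#' @return named list (by subject id) of `lowpoint_series` data frames
#'   with columns `percent_cycle`, `medial_ap`, `lateral_ap`,
#'   `medial_ml`, `lateral_ml`.
#' @export
gen_lowpoint_trajectories <- function(activity, subjects,
                                      mean_shape_params =
                                        default_lowpoint_shape(activity$activity),
                                      sd_medial = 1.2, sd_lateral = 1.9,
                                      intercondylar_distance = 49,
                                      n_harmonics = 3L) {
  stopifnot(inherits(activity, "activity_spec"))
  if (!is.finite(sd_medial) || sd_medial < 0 ||
      !is.finite(sd_lateral) || sd_lateral < 0)
    stop("sd values must be finite and >= 0")
  check_coefs <- function(cf) {
    if (!all(is.finite(unlist(cf)))) stop("non-finite shape parameters")
  }
  check_coefs(mean_shape_params$medial)
  check_coefs(mean_shape_params$lateral)
  pct <- cycle_grid(activity)
  mean_med <- fourier_eval(mean_shape_params$medial, pct)
  mean_lat <- fourier_eval(mean_shape_params$lateral, pct)
  # variance split: half in a constant offset, the rest decaying over
  # harmonics, so the pointwise deviation SD equals the target exactly
  w <- c(0.5, 0.5 * rev(seq_len(n_harmonics)) / sum(seq_len(n_harmonics)))
  draw_dev <- function(sd) {
    off <- stats::rnorm(1L, 0, sqrt(w[1]) * sd)
    dev <- rep(off, length(pct))
    th <- pct / 100 * 2 * pi
    for (k in seq_len(n_harmonics)) {
      sk <- sqrt(w[k + 1L]) * sd
      dev <- dev + stats::rnorm(1L, 0, sk) * cos(k * th) +
        stats::rnorm(1L, 0, sk) * sin(k * th)
    }
    dev
  }
  out <- lapply(subjects, function(s) {
    with_seed(substream_seed(s$seed, "lowpoints", activity$activity,
                             s$subject_id), {
      df <- data.frame(percent_cycle = pct,
                       medial_ap = mean_med + draw_dev(sd_medial),
                       lateral_ap = mean_lat + draw_dev(sd_lateral),
                       medial_ml = intercondylar_distance / 2,
                       lateral_ml = -intercondylar_distance / 2)
      class(df) <- c("lowpoint_series", "data.frame")
      df
    })
  })
  names(out) <- vapply(subjects, `[[`, character(1), "subject_id")
  out
}

#' Default load-waveform control peaks
#'
#' Named control points (percent cycle, value) for the tibiofemoral
#' compression and quadriceps force profiles of each activity, scaled to
#' a 66 kg person. Quadriceps gait peaks default to 651 N in early stance
#' and 271 N at swing initiation; stair-descent quadriceps peaks to
#' 645 N near heel strike, 582 N in mid-stance and 251 N at toe-off; the
#' sit-stand quadriceps peak to 660 N at maximum flexion. Compression
#' anchors are chosen so that peak articular compression (applied plus
#' extensor contribution) lands in the 1.5-2.5 kN range typical of these
#' activities.
#'
#' @param activity activity name.
#' @return list of data frames (`percent`, `value`), one per quantity.
#' @export
default_load_peaks <- function(activity = c("gait", "stair_descent",
                                            "sit_stand")) {
  activity <- match.arg(activity)
  pk <- function(...) {
    m <- matrix(c(...), ncol = 2L, byrow = TRUE)
    data.frame(percent = m[, 1], value = m[, 2])
  }
  switch(activity,
    gait = list(
      tf_compression = pk(0, 350, 17, 1450, 32, 800, 48, 1200, 62, 400,
                          100, 350),
      quadriceps = pk(0, 30, 15, 651, 45, 100, 72, 271, 100, 30)),
    stair_descent = list(
      tf_compression = pk(0, 500, 15, 1800, 40, 1100, 55, 1400, 75, 300,
                          100, 500),
      quadriceps = pk(0, 400, 5, 645, 25, 350, 45, 582, 60, 251, 80, 80,
                      100, 400)),
    sit_stand = list(
      tf_compression = pk(0, 600, 35, 1300, 50, 1500, 65, 1300, 100, 600),
      quadriceps = pk(0, 50, 50, 660, 100, 50)))
}

#' Generate smooth load waveforms through named peaks
#'
#' Builds one waveform per quantity by C1 piecewise-cubic Hermite
#' interpolation with zero slope at every control point (no overshoot),
#' so each named peak value is attained exactly at its location. Control
#' points at 0% and 100% anchor the cycle; if absent they are added at
#' zero.
#'
#' @param activity an [activity_spec()].
#' @param peaks named list of data frames with columns `percent` (in
#'   `[0, 100]`) and `value` (finite), as [default_load_peaks()].
#' @param units named character vector of units per quantity (defaults:
#'   N).
#' @return named list of [waveform()]s on the activity grid.
#' @export
#' @examples
#' act <- activity_spec("gait")
#' wf <- gen_load_waveforms(act)
#' max(wf$quadriceps$values)   # 651
gen_load_waveforms <- function(activity, peaks = default_load_peaks(activity$activity),
                               units = NULL) {
  stopifnot(inherits(activity, "activity_spec"))
  pct <- cycle_grid(activity)
  out <- lapply(names(peaks), function(q) {
    p <- peaks[[q]]
    if (!all(is.finite(p$value)) || !all(is.finite(p$percent)))
      stop("non-finite peak specification")
    if (any(p$percent < 0 | p$percent > 100))
      stop("peak locations must lie in [0, 100]%")
    p <- p[order(p$percent), , drop = FALSE]
    if (anyDuplicated(p$percent)) stop("duplicate peak locations")
    if (p$percent[1] > 0) p <- rbind(data.frame(percent = 0, value = 0), p)
    if (p$percent[nrow(p)] < 100)
      p <- rbind(p, data.frame(percent = 100, value = 0))
    vals <- peak_interp(p$percent, p$value, pct)
    waveform(pct, vals, quantity = q,
             units = (units %||% character(0))[q] %|NA|% "N",
             activity = activity$activity)
  })
  names(out) <- names(peaks)
  out
}

`%|NA|%` <- function(x, y) if (length(x) == 0L || is.na(x)) y else x

# C1 piecewise-cubic interpolation with zero slope at every control
# point (Hermite smoothstep per segment): monotone between neighboring
# control points, so each named peak value is attained exactly and never
# overshot.
peak_interp <- function(x, y, xout) {
  idx <- findInterval(xout, x, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(x) - 1L)
  s <- (xout - x[idx]) / (x[idx + 1L] - x[idx])
  s <- pmin(pmax(s, 0), 1)
  y[idx] + (y[idx + 1L] - y[idx]) * (3 * s^2 - 2 * s^3)
}

#' Generate an idealized implant geometry
#'
#' Builds a femoral component whose condyles are spheres and a tibial
#' insert whose articular dishes are spherical troughs, as triangulated
#' meshes plus the analytic surface parameters, so mesh-based operations
#' (low points, registration) can be checked against closed forms. The
#' femoral condyle spheres of radius `condyle_radius` are centered at
#' height `condyle_radius` above the tray plane and `+/-
#' intercondylar_distance / 2` medial-laterally, so the analytic sphere
#' bottoms touch the plane at height 0. The insert dish spheres share
#' the condylar centers laterally with radius `dish_radius`.
#'
#' @param condyle_radius mm, `> 0`.
#' @param intercondylar_distance mm, `> 0`.
#' @param dish_radius mm, `>= condyle_radius`.
#' @param n_seg mesh refinement (longitudinal segments per sphere).
#' @return list with `femur` and `insert` ([trimesh()]s, frame: x
#'   anterior, y superior, z medial) and `params` (analytic centers and
#'   radii).
#' @export
gen_implant_geometry <- function(condyle_radius = 25,
                                 intercondylar_distance = 49,
                                 dish_radius = 30, n_seg = 24L) {
  if (!is.finite(condyle_radius) || condyle_radius <= 0)
    stop("condyle_radius must be > 0")
  if (!is.finite(intercondylar_distance) || intercondylar_distance <= 0)
    stop("intercondylar_distance must be > 0")
  if (!is.finite(dish_radius) || dish_radius < condyle_radius)
    stop("dish_radius must be >= condyle_radius")
  half <- intercondylar_distance / 2
  centers <- rbind(medial = c(0, condyle_radius, half),
                   lateral = c(0, condyle_radius, -half))
  sphere_pair <- function(r, h) {
    merge_meshes(
      uv_sphere_mesh(r, c(0, h, half), n_seg),
      uv_sphere_mesh(r, c(0, h, -half), n_seg))
  }
  list(femur = sphere_pair(condyle_radius, condyle_radius),
       insert = sphere_pair(dish_radius, dish_radius),
       params = list(condyle_radius = condyle_radius,
                     dish_radius = dish_radius,
                     intercondylar_distance = intercondylar_distance,
                     condyle_centers = centers,
                     bottom_height = 0))
}

#' Default calibration bead table
#'
#' Thirteen beads: one at the tray centroid plus two concentric rings of
#' six, covering the tray plane so the three load outputs are
#' identifiable.
#'
#' @return data frame with `bead_id`, `x`, `y` (mm, centroid origin).
#' @export
default_bead_table <- function() {
  ang1 <- seq(0, 2 * pi, length.out = 7L)[-7L]
  ang2 <- ang1 + pi / 6
  df <- data.frame(
    bead_id = paste0("B", sprintf("%02d", 1:13)),
    x = c(0, 20 * cos(ang1), 35 * cos(ang2)),
    y = c(0, 20 * sin(ang1), 35 * sin(ang2)))
  df$x <- round(df$x, 6)
  df$y <- round(df$y, 6)
  df
}

#' Generate synthetic tray channel readings for a bead-loading sweep
#'
#' Simulates the bead calibration experiment: a known axial force at
#' each bead location creates known loads ([expected_loads()]); channel
#' readings follow the pseudo-inverse gain model of a known true
#' calibration matrix, plus optional Gaussian channel noise.
#'
#' @param true_matrix a [calibration_matrix()] (full row rank).
#' @param beads bead table as [default_bead_table()].
#' @param applied_force axial force per bead, N.
#' @param noise_sd channel noise SD (channel units).
#' @param seed RNG seed for the noise.
#' @return list with `readings` (Kx4), `known_loads` (Kx3), `beads`.
#' @export
gen_tray_readings <- function(true_matrix, beads = default_bead_table(),
                              applied_force = 1000, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(true_matrix, "calibration_matrix"))
  if (nrow(beads) < 3L) stop("need at least 3 beads")
  loads <- expected_loads(cbind(beads$x, beads$y), applied_force)
  M <- true_matrix$matrix
  s <- svd(M)
  if (s$d[3] < 1e-10 * s$d[1]) stop("true_matrix is not full row rank")
  pinvM <- s$v %*% (1 / s$d * t(s$u))      # 4x3
  readings <- loads %*% t(pinvM)
  if (noise_sd > 0)
    readings <- readings + with_seed(substream_seed(seed, "tray_readings"),
      matrix(stats::rnorm(length(readings), 0, noise_sd), nrow(readings)))
  colnames(readings) <- paste0("q", 1:4)
  list(readings = readings, known_loads = loads, beads = beads)
}

#' Generate noisy observed fiducial point sets for a pose series
#'
#' @param poses list of [pose()]s.
#' @param fiducials Nx3 matrix of marker positions in the body frame,
#'   `N >= 3`, non-collinear.
#' @param noise_sd isotropic noise SD, mm.
#' @param seed RNG seed.
#' @return list of observed Nx3 point sets, one per pose.
#' @export
gen_marker_data <- function(poses, fiducials, noise_sd = 0, seed = 1L) {
  fiducials <- unname(as.matrix(fiducials))
  if (nrow(fiducials) < 3L) stop("need at least 3 fiducials")
  sv <- svd(sweep(fiducials, 2L, colMeans(fiducials)), nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12))
    stop("collinear fiducial set: registration unsolvable")
  with_seed(substream_seed(seed, "marker_data"), {
    lapply(poses, function(p) {
      pts <- pose_apply(p, fiducials)
      if (noise_sd > 0)
        pts <- pts + matrix(stats::rnorm(length(pts), 0, noise_sd), nrow(pts))
      pts
    })
  })
}

#' Default knee flexion waveform per activity
#'
#' Smooth flexion-extension traces with the canonical morphology: gait
#' with a small stance peak and a large swing peak, stair descent with
#' deep swing flexion, and sit-stand rising to peak flexion at 50% of
#' the cycle. The cycle starts at the most extended flexion, matching
#' the synchronization convention.
#'
#' @param activity an [activity_spec()].
#' @return a [waveform()] in degrees.
#' @export
default_flexion_waveform <- function(activity) {
  stopifnot(inherits(activity, "activity_spec"))
  pct <- cycle_grid(activity)
  pts <- switch(activity$activity,
    gait = cbind(c(0, 15, 40, 73, 100), c(5, 20, 8, 60, 5)),
    stair_descent = cbind(c(0, 20, 45, 75, 100), c(10, 25, 15, 90, 10)),
    sit_stand = cbind(c(0, 50, 100), c(5, 90, 5)))
  vals <- peak_interp(pts[, 1], pts[, 2], pct)
  waveform(pct, vals, quantity = "flexion", units = "deg",
           activity = activity$activity)
}
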