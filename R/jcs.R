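#' Construct a Grood-Suntay joint coordinate system state
#'
#' The six clinical degrees of freedom of the tibiofemoral joint:
#' flexion-extension, adduction-abduction, and internal-external rotation
#' (degrees), plus medial-lateral, anterior-posterior, and
#' superior-inferior translation (mm). Sign conventions (right knee):
#' flexion positive, adduction positive, internal tibial rotation
#' positive, lateral / anterior / superior tibial translation positive.
#'
#' @param flexion_extension,adduction_abduction,internal_external degrees.
#' @param medial_lateral,anterior_posterior,superior_inferior mm.
#' @return an object of class `"jcs_state"`.
#' @export
jcs_state <- function(flexion_extension = 0, adduction_abduction = 0,
                      internal_external = 0, medial_lateral = 0,
                      anterior_posterior = 0, superior_inferior = 0) {
  x <- c(flexion_extension = flexion_extension,
         adduction_abduction = adduction_abduction,
         internal_external = internal_external,
         medial_lateral = medial_lateral,
         anterior_posterior = anterior_posterior,
         superior_inferior = superior_inferior)
  if (!all(is.finite(x))) stop("jcs_state components must be finite")
  structure(as.list(x), class = "jcs_state")
}

#' @export
print.jcs_state <- function(x, ...) {
  cat(sprintf(paste0("<jcs_state> F-E %.2f, Ad-Ab %.2f, I-E %.2f deg; ",
                     "M-L %.2f, A-P %.2f, S-I %.2f mm\n"),
              x$flexion_extension, x$adduction_abduction, x$internal_external,
              x$medial_lateral, x$anterior_posterior, x$superior_inferior))
  invisible(x)
}

# JCS axis bookkeeping. In the femoral frame (x anterior, y superior,
# z lateral) the femoral fixed axis e1 is the z axis (flexion axis), the
# tibial fixed axis e3 is the tibial y axis (long axis, internal-external
# rotation), and the floating axis e2 = e3 x e1 (normalized) points
# anterior at neutral. The relative rotation decomposes as the intrinsic
# sequence Rz(-flexion) Rx(adduction) Ry(internal).
jcs_relative_rotation <- function(flexion, adduction, internal) {
  rot_z(-flexion) %*% rot_x(adduction) %*% rot_y(internal)
}

#' Grood-Suntay decomposition of a relative femur-tibia pose
#'
#' Decomposes the pose of the tibia relative to the femur into the six
#' Grood-Suntay degrees of freedom. The femoral fixed axis is the femoral
#' medio-lateral (z) axis, the tibial fixed axis is the tibial long (y)
#' axis, and the floating anterior axis is their normalized cross
#' product. Translations are the components of the tibial origin in the
#' (non-orthogonal) joint-coordinate basis, which makes the decomposition
#' exactly invertible by [poses_from_jcs()].
#'
#' @param femur_pose,tibia_pose [pose()]s of the femoral and tibial
#'   anatomical frames in a common world frame.
#' @return a [jcs_state()]. Configurations with `|Ad-Ab| > 80` degrees are
#'   flagged via the `"gimbal_proximal"` attribute (`TRUE`).
#' @seealso [poses_from_jcs()] for the exact inverse.
#' @export
#' @examples
#' f <- pose(); t <- pose(rot_z(-30))         # pure 30 deg flexion
#' jcs_from_poses(f, t)$flexion_extension
jcs_from_poses <- function(femur_pose, tibia_pose) {
  stopifnot(inherits(femur_pose, "pose"), inherits(tibia_pose, "pose"))
  check_rotation(femur_pose$rotation)
  check_rotation(tibia_pose$rotation)
  R <- crossprod(femur_pose$rotation, tibia_pose$rotation)
  t_rel <- drop(crossprod(femur_pose$rotation,
                          tibia_pose$translation - femur_pose$translation))
  # intrinsic z-x-y extraction: R = Rz(a) Rx(b) Ry(c)
  b <- asin(max(-1, min(1, R[3, 2])))
  a <- atan2(-R[1, 2], R[2, 2])
  c_ <- atan2(-R[3, 1], R[3, 3])
  deg <- 180 / pi
  e1 <- c(0, 0, 1)
  e3 <- R[, 2]
  e2 <- cross3(e3, e1)
  n2 <- sqrt(sum(e2^2))
  if (n2 < 1e-9) stop("gimbal lock: tibial long axis parallel to flexion axis")
  e2 <- e2 / n2
  q <- as.numeric(solve(cbind(e1, e2, e3), t_rel))
  out <- jcs_state(flexion_extension = -a * deg,
                   adduction_abduction = b * deg,
                   internal_external = c_ * deg,
                   medial_lateral = q[1],
                   anterior_posterior = q[2],
                   superior_inferior = q[3])
  if (abs(out$adduction_abduction) > 80)
    attr(out, "gimbal_proximal") <- TRUE
  out
}

#' Compose a relative pose from a Grood-Suntay state
#'
#' Exact inverse of [jcs_from_poses()] away from gimbal lock: returns the
#' pose of the tibial frame expressed in the femoral frame.
#'
#' @param jcs a [jcs_state()].
#' @return a [pose()] with `from_frame = "tibia"`, `to_frame = "femur"`.
#' @export
poses_from_jcs <- function(jcs) {
  stopifnot(inherits(jcs, "jcs_state"))
  if (abs(jcs$adduction_abduction) >= 90 - 1e-9)
    stop("gimbal-locked jcs_state: |Ad-Ab| must be < 90 degrees")
  R <- jcs_relative_rotation(jcs$flexion_extension, jcs$adduction_abduction,
                             jcs$internal_external)
  e1 <- c(0, 0, 1)
  e3 <- R[, 2]
  e2 <- cross3(e3, e1)
  e2 <- e2 / sqrt(sum(e2^2))
  t_rel <- jcs$medial_lateral * e1 + jcs$anterior_posterior * e2 +
    jcs$superior_inferior * e3
  pose(R, t_rel, from_frame = "tibia", to_frame = "femur")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
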