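#' Convert condylar low-point translations to I-E rotation and A-P translation
#'
#' Under the Grood-Suntay convention the two condylar anterior-posterior
#' low-point translations determine the transverse-plane state of the
#' joint: the internal-external rotation follows from the difference of
#' the condylar translations over the intercondylar distance, and the
#' anterior-posterior translation is their unweighted midpoint. With the
#' right-knee sign convention (anterior positive, internal tibial
#' rotation positive), a medial condyle anterior to the lateral condyle
#' corresponds to positive internal rotation:
#' `ie = atan2(medial_ap - lateral_ap, distance)`.
#'
#' @param medial_ap,lateral_ap condylar A-P low-point translations (mm).
#' @param intercondylar_distance medial-lateral distance between the
#'   condylar low-point tracks (mm), `> 0`.
#' @return list with `internal_external` (deg) and `anterior_posterior`
#'   (mm). Vectorized over the translations.
#' @seealso [ie_ap_to_lowpoints()] for the exact inverse.
#' @export
#' @examples
#' lowpoints_to_ie_ap(3.05, -3.05, 49)  # ie = atan(6.1 / 49) = 7.10 deg
lowpoints_to_ie_ap <- function(medial_ap, lateral_ap, intercondylar_distance) {
  if (!is.finite(intercondylar_distance) || intercondylar_distance <= 0)
    stop("intercondylar_distance must be > 0")
  list(internal_external = atan2(medial_ap - lateral_ap,
                                 intercondylar_distance) * 180 / pi,
       anterior_posterior = (medial_ap + lateral_ap) / 2)
}

#' @rdname lowpoints_to_ie_ap
#' @param internal_external internal-external rotation (deg).
#' @param anterior_posterior A-P translation (mm).
#' @export
ie_ap_to_lowpoints <- function(internal_external, anterior_posterior,
                               intercondylar_distance) {
  if (!is.finite(intercondylar_distance) || intercondylar_distance <= 0)
    stop("intercondylar_distance must be > 0")
  half <- intercondylar_distance / 2 * tan(internal_external * pi / 180)
  list(medial_ap = anterior_posterior + half,
       lateral_ap = anterior_posterior - half)
}

#' Decompose a patellofemoral load into patellar anatomic components
#'
#' Rotates a load vector measured in the tray (world) frame into the
#' patellar anatomic frame and reports its components along the articular
#' surface: anterior, medial, and superior. The decomposition is an
#' isometry, so the vector magnitude is preserved.
#'
#' @param load_vector length-3 force vector (N) in the tray/world frame.
#' @param patella_pose [pose()] of the patellar anatomic frame (x
#'   anterior, y superior, z lateral) in the same world frame.
#' @return named numeric vector `c(anterior, medial, superior)` in N.
#' @export
decompose_pf_load <- function(load_vector, patella_pose) {
  stopifnot(inherits(patella_pose, "pose"), length(load_vector) == 3L)
  v <- drop(crossprod(patella_pose$rotation, as.numeric(load_vector)))
  c(anterior = v[1], medial = -v[3], superior = v[2])
}
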