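#' Instrumented tibial tray calibration
#'
#' An instrumented tibial tray houses four uniaxial button load cells,
#' one per quadrant, and reports superior-inferior (S-I) force, the
#' adduction-abduction (Ad-Ab) moment, and the flexion-extension (F-E)
#' moment about the tray centroid. Calibration loads the tray through a
#' block of steel beads at known tray-plane locations with a known axial
#' force, and solves the linear map from the four channel readings to the
#' three loads.
#'
#' @name tray_calibration
NULL

#' Construct a calibration matrix
#'
#' @param matrix 3x4 numeric matrix mapping the four channel readings to
#'   `(S-I force N, Ad-Ab moment Nmm, F-E moment Nmm)`.
#' @param residual_rms optional per-output residual RMS from the solve.
#' @return an object of class `"calibration_matrix"`.
#' @export
calibration_matrix <- function(matrix, residual_rms = c(NA_real_, NA_real_, NA_real_)) {
  matrix <- unname(as.matrix(matrix))
  if (!all(dim(matrix) == c(3L, 4L))) stop("calibration matrix must be 3x4")
  if (!all(is.finite(matrix))) stop("non-finite calibration entries")
  structure(list(matrix = matrix,
                 outputs = c("si_force_N", "adab_moment_Nmm", "fe_moment_Nmm"),
                 channels = paste0("q", 1:4),
                 residual_rms = residual_rms),
            class = "calibration_matrix")
}

#' @export
print.calibration_matrix <- function(x, ...) {
  cat("<calibration_matrix> channels q1..q4 ->",
      paste(x$outputs, collapse = ", "), "\n")
  print(round(x$matrix, 6))
  invisible(x)
}

#' Known loads created by an axial bead-point load
#'
#' A purely axial force applied at tray-plane location `(x, y)` creates a
#' known S-I force equal to the applied force and known moments about the
#' tray centroid. Convention: `x` is the tray anterior-posterior
#' coordinate, `y` the medial-lateral coordinate (mm, centroid at the
#' origin); the Ad-Ab moment (about the A-P axis) is `force * y` and the
#' F-E moment (about the M-L axis) is `force * x`, i.e. signed lever
#' arms.
#'
#' @param bead length-2 numeric `(x, y)` in mm, or a Kx2 matrix.
#' @param force applied axial force in N, `> 0`.
#' @return numeric vector `(fz, m_adab, m_fe)` in (N, Nmm, Nmm), or a Kx3
#'   matrix for matrix input.
#' @export
#' @examples
#' expected_loads(c(10, 0))   # 1000 N, 0 Nmm Ad-Ab, 10000 Nmm F-E
expected_loads <- function(bead, force = 1000) {
  if (!is.finite(force) || force <= 0) stop("force must be > 0")
  if (is.null(dim(bead))) {
    stopifnot(length(bead) == 2L)
    return(c(fz = force, m_adab = force * bead[2], m_fe = force * bead[1]))
  }
  bead <- as.matrix(bead)
  cbind(fz = rep(force, nrow(bead)), m_adab = force * bead[, 2],
        m_fe = force * bead[, 1])
}

#' Solve the tray calibration matrix from a bead-loading experiment
#'
#' Least-squares fit of the 3x4 map from channel readings to known loads,
#' minimizing the error between load-cell derived loads and the loads
#' applied by the load frame. The minimum-norm least-squares solution
#' (SVD pseudo-inverse) is used: because the channels respond linearly to
#' a 3-dimensional load space, a noiseless calibration sweep spans only 3
#' of the 4 channel dimensions and the minimum-norm solution is then the
#' unique physically consistent matrix.
#'
#' @param readings Kx4 matrix of channel readings, `K >= 4`.
#' @param known_loads Kx3 matrix of applied `(fz, m_adab, m_fe)` loads.
#' @param rank_tol relative singular-value tolerance for the effective
#'   rank of `readings`.
#' @return a [calibration_matrix()] with per-output residual RMS.
#' @export
solve_calibration <- function(readings, known_loads, rank_tol = 1e-10) {
  C <- unname(as.matrix(readings))
  L <- unname(as.matrix(known_loads))
  if (ncol(C) != 4L) stop("readings must have 4 channels")
  if (ncol(L) != 3L) stop("known_loads must have 3 outputs")
  if (nrow(C) != nrow(L)) stop("readings and known_loads row counts differ")
  if (nrow(C) < 4L) stop("need at least 4 loading cases")
  s <- svd(C)
  rank <- sum(s$d > rank_tol * s$d[1])
  if (rank < 3L)
    stop(sprintf(paste0("rank-deficient readings: channel data span only ",
                        "%d dimension(s); at least 3 independent load ",
                        "directions are required"), rank))
  dinv <- ifelse(s$d > rank_tol * s$d[1], 1 / s$d, 0)
  pinvC <- s$v %*% (dinv * t(s$u))
  M <- t(pinvC %*% L)
  resid <- L - C %*% t(M)
  calibration_matrix(M, residual_rms = sqrt(colMeans(resid^2)))
}

#' Apply a calibration matrix to channel readings
#'
#' @param cal a [calibration_matrix()].
#' @param readings length-4 vector or Kx4 matrix of channel readings.
#' @return length-3 vector or Kx3 matrix of `(fz, m_adab, m_fe)` loads.
#' @export
apply_calibration <- function(cal, readings) {
  stopifnot(inherits(cal, "calibration_matrix"))
  if (is.null(dim(readings))) {
    if (length(readings) != 4L) stop("expected 4 channel readings")
    return(drop(cal$matrix %*% as.numeric(readings)))
  }
  readings <- as.matrix(readings)
  if (ncol(readings) != 4L) stop("expected 4 channel columns")
  out <- readings %*% t(cal$matrix)
  colnames(out) <- cal$outputs
  out
}
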