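#' Least-squares rigid registration of paired point sets (Kabsch)
#'
#' Finds the rigid transform `x -> R x + t` minimizing the sum of squared
#' distances between transformed `model_points` and `observed_points`
#' (known correspondence), via singular value decomposition of the
#' cross-covariance with the proper-rotation sign correction.
#'
#' @param model_points,observed_points Nx3 matrices of corresponding
#'   points, `N >= 3`, model points not all collinear.
#' @return a list with `pose` (the optimal [pose()]) and `rms` (root mean
#'   square residual distance, mm).
#' @export
#' @examples
#' pts <- matrix(rnorm(30), 10, 3)
#' fit <- kabsch_fit(pts, pose_apply(pose(rot_z(30), c(1, 0, 0)), pts))
#' fit$rms   # ~ 0
kabsch_fit <- function(model_points, observed_points) {
  A <- unname(as.matrix(model_points))
  B <- unname(as.matrix(observed_points))
  if (!all(dim(A) == dim(B)) || ncol(A) != 3L)
    stop("point sets must be matching Nx3 matrices")
  if (nrow(A) < 3L) stop("need at least 3 correspondences")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  sv_model <- svd(A0, nu = 0, nv = 0)$d
  if (sv_model[2] < 1e-9 * max(sv_model[1], 1e-12))
    stop("degenerate (collinear) model points: rotation not identifiable")
  H <- crossprod(A0, B0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cb - drop(R %*% ca)
  resid <- B - (A %*% t(R) + rep(t, each = nrow(A)))
  list(pose = pose(R, t, from_frame = "model", to_frame = "observed"),
       rms = sqrt(mean(rowSums(resid^2))))
}

#' Iterative closest point registration of a mesh to a point cloud
#'
#' Aligns a surface mesh to a digitized point cloud by alternating
#' nearest-vertex correspondence with Kabsch fits (point-to-point metric,
#' all-point correspondence, no outlier trimming: intended for small,
#' clean, desk-scale clouds). The residual history is monotone
#' non-increasing. Convergence within the documented capture range
#' (initial pose within a few mm / few degrees) is assumed, as for any
#' local ICP.
#'
#' @param mesh a [trimesh()].
#' @param cloud Nx3 matrix of measured points.
#' @param initial initial [pose()] estimate (mesh -> cloud frame).
#' @param max_iter maximum iterations.
#' @param tol stop when the RMS residual improves by less than `tol` mm.
#' @return list with `pose`, `rms`, `residual_history`, `iterations`,
#'   `converged`.
#' @export
icp_fit <- function(mesh, cloud, initial = pose(), max_iter = 50L,
                    tol = 1e-9) {
  stopifnot(inherits(mesh, "trimesh"))
  cloud <- unname(as.matrix(cloud))
  if (nrow(cloud) == 0L) stop("empty point cloud")
  if (ncol(cloud) != 3L) stop("cloud must be Nx3")
  cur <- initial
  history <- numeric(0)
  for (it in seq_len(max_iter)) {
    posed <- pose_apply(cur, mesh$vertices)
    nn <- nearest_index(posed, cloud)
    fit <- kabsch_fit(mesh$vertices[nn, , drop = FALSE], cloud)
    cur <- fit$pose
    history <- c(history, fit$rms)
    if (it > 1L && history[it - 1L] - history[it] < tol) break
  }
  list(pose = cur, rms = history[length(history)],
       residual_history = history, iterations = length(history),
       converged = length(history) < max_iter ||
         (length(history) > 1L && diff(utils::tail(history, 2L)) > -tol))
}

# For each query row, index of the nearest reference row (brute force,
# chunked to bound memory).
nearest_index <- function(reference, query, chunk = 512L) {
  rn <- rowSums(reference^2)
  out <- integer(nrow(query))
  for (start in seq(1L, nrow(query), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(query))
    q <- query[idx, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rn, "+") - 2 * q %*% t(reference)
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  out
}
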