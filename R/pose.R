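#' Construct a rigid-body pose
#'
#' A pose is a proper rigid transform `x -> R x + t` mapping coordinates
#' from `from_frame` into `to_frame`.
#'
#' @param rotation 3x3 proper orthogonal matrix (`det = +1`, orthogonal to
#'   1e-9).
#' @param translation length-3 numeric vector (mm).
#' @param from_frame,to_frame frame labels.
#' @return an object of class `"pose"`.
#' @export
#' @examples
#' p <- pose(rot_z(30), c(1, 2, 3))
#' q <- pose_compose(p, pose_invert(p))   # identity
pose <- function(rotation = diag(3), translation = c(0, 0, 0),
                 from_frame = "body", to_frame = "world") {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3x3")
  if (length(translation) != 3L) stop("translation must have length 3")
  check_rotation(rotation)
  structure(list(rotation = rotation, translation = translation,
                 from_frame = from_frame, to_frame = to_frame),
            class = "pose")
}

check_rotation <- function(R, tol = 1e-9) {
  if (!all(is.finite(R))) stop("rotation contains non-finite entries")
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("rotation is not orthogonal within tolerance")
  if (abs(det(R) - 1) > tol)
    stop("rotation determinant is not +1 (improper rotation)")
  invisible(R)
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> %s -> %s, translation (%.3f, %.3f, %.3f) mm\n",
              x$from_frame, x$to_frame,
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a pose to points
#'
#' @param p a [pose()].
#' @param pts Nx3 matrix (or length-3 vector) of points.
#' @return transformed points, same shape.
#' @export
pose_apply <- function(p, pts) {
  if (is.null(dim(pts))) return(drop(p$rotation %*% pts + p$translation))
  t(p$rotation %*% t(pts)) + rep(p$translation, each = nrow(pts))
}

#' @rdname pose_apply
#' @param a,b poses; `pose_compose(a, b)` maps first through `b`, then `a`.
#' @export
pose_compose <- function(a, b) {
  pose(a$rotation %*% b$rotation,
       drop(a$rotation %*% b$translation) + a$translation,
       from_frame = b$from_frame, to_frame = a$to_frame)
}

#' @rdname pose_apply
#' @export
pose_invert <- function(p) {
  pose(t(p$rotation), drop(-t(p$rotation) %*% p$translation),
       from_frame = p$to_frame, to_frame = p$from_frame)
}

#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, angle in degrees.
#'
#' @param deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rot_x <- function(deg) {
  a <- deg * pi / 180; c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(deg) {
  a <- deg * pi / 180; c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(deg) {
  a <- deg * pi / 180; c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary axis (Rodrigues formula)
#'
#' @param axis length-3 axis vector (normalized internally).
#' @param deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rot_axis_angle <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
}
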