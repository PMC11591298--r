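#' Construct a triangulated surface mesh
#'
#' @param vertices Nx3 numeric matrix of vertex coordinates (mm).
#' @param faces Mx3 integer matrix of 1-based vertex indices.
#' @return an object of class `"trimesh"`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- unname(as.matrix(vertices))
  faces <- unname(as.matrix(faces))
  if (ncol(vertices) != 3L) stop("vertices must be Nx3")
  if (ncol(faces) != 3L) stop("faces must be Mx3")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  storage.mode(faces) <- "integer"
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
    stop("degenerate faces (repeated vertex index)")
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Unit-sphere mesh with poles on the +/- z axis; n_seg longitudinal
# segments, n_seg/2 latitudinal bands. Watertight (shared pole vertices).
uv_sphere_mesh <- function(radius = 1, center = c(0, 0, 0), n_seg = 24L) {
  n_seg <- as.integer(n_seg)
  if (n_seg < 6L) stop("n_seg must be >= 6")
  n_lat <- max(3L, n_seg %/% 2L)           # interior latitude rings
  theta <- seq(0, pi, length.out = n_lat + 2L)[-c(1L, n_lat + 2L)]
  phi <- seq(0, 2 * pi, length.out = n_seg + 1L)[-(n_seg + 1L)]
  ring <- function(th) cbind(sin(th) * cos(phi), sin(th) * sin(phi),
                             rep(cos(th), n_seg))
  verts <- do.call(rbind, lapply(theta, ring))
  top <- nrow(verts) + 1L
  bot <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, 1), c(0, 0, -1))
  idx <- function(i, j) (i - 1L) * n_seg + ((j - 1L) %% n_seg) + 1L
  faces <- list()
  for (j in seq_len(n_seg)) {
    faces[[length(faces) + 1L]] <- c(top, idx(1L, j), idx(1L, j + 1L))
    faces[[length(faces) + 1L]] <- c(bot, idx(n_lat, j + 1L), idx(n_lat, j))
  }
  for (i in seq_len(n_lat - 1L)) for (j in seq_len(n_seg)) {
    a <- idx(i, j); b <- idx(i, j + 1L); cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    faces[[length(faces) + 1L]] <- c(a, b, d)
    faces[[length(faces) + 1L]] <- c(a, d, cc)
  }
  trimesh(verts * radius + rep(center, each = nrow(verts)),
          do.call(rbind, faces))
}

merge_meshes <- function(a, b) {
  trimesh(rbind(a$vertices, b$vertices),
          rbind(a$faces, b$faces + nrow(a$vertices)))
}

#' Define a tibial tray coordinate frame
#'
#' The tray frame carries the plane of the tibial tray: `origin` on the
#' plane, `up` the plane normal (superior), `anterior` the in-plane
#' anterior-posterior axis, and the medial axis completing a right-handed
#' set. Condylar low points are reported in this frame with medial
#' positive.
#'
#' @param origin point on the tray plane (mm).
#' @param anterior approximate anterior direction (projected in-plane).
#' @param up tray plane normal, superior positive.
#' @param medial_hint optional vector used to orient the medial axis; the
#'   computed medial axis is flipped to have positive dot product with it.
#' @return an object of class `"tray_frame"`.
#' @export
tray_frame <- function(origin = c(0, 0, 0), anterior = c(1, 0, 0),
                       up = c(0, 1, 0), medial_hint = NULL) {
  up <- up / sqrt(sum(up^2))
  anterior <- anterior - sum(anterior * up) * up
  na <- sqrt(sum(anterior^2))
  if (na < 1e-9) stop("anterior direction parallel to tray normal")
  anterior <- anterior / na
  medial <- cross3(up, anterior)
  # the tray frame is a coordinate chart, not a rotation: flip the medial
  # axis alone if the caller's hint points the other way
  if (!is.null(medial_hint) && sum(medial * medial_hint) < 0)
    medial <- -medial
  structure(list(origin = as.numeric(origin), anterior = anterior,
                 medial = medial, up = up), class = "tray_frame")
}

# Points (world) -> tray-frame coordinates (ap, ml, height).
tray_coords <- function(frame, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1L)
  d <- pts - rep(frame$origin, each = nrow(pts))
  out <- cbind(drop(d %*% frame$anterior), drop(d %*% frame$medial),
               drop(d %*% frame$up))
  colnames(out) <- c("ap", "ml", "height")
  out
}

#' Construct a condylar low-point record
#'
#' Per-condyle lowest-point coordinates above the tibial tray plane, in
#' the tray frame (anterior positive, medial positive).
#'
#' @param medial_ap,lateral_ap anterior-posterior coordinates (mm).
#' @param medial_ml,lateral_ml medial-lateral coordinates (mm); the two
#'   condyles must lie on opposite sides of the sagittal split plane.
#' @param height_medial,height_lateral heights above the tray plane (mm).
#' @return an object of class `"condylar_lowpoints"`.
#' @export
condylar_lowpoints <- function(medial_ap, lateral_ap, medial_ml, lateral_ml,
                               height_medial = 0, height_lateral = 0) {
  x <- list(medial_ap = medial_ap, lateral_ap = lateral_ap,
            medial_ml = medial_ml, lateral_ml = lateral_ml,
            height_medial = height_medial, height_lateral = height_lateral)
  if (!all(vapply(x, is.finite, logical(1)))) stop("non-finite low points")
  if (medial_ml * lateral_ml > 0)
    stop("medial and lateral low points must straddle the sagittal split")
  structure(x, class = "condylar_lowpoints")
}

#' Femoral condylar low points relative to the tibial tray plane
#'
#' Poses a femoral component mesh, splits its vertices into medial and
#' lateral condyles at a sagittal plane, and returns the vertex of each
#' condyle with minimal signed height above the tray plane, in tray-frame
#' coordinates. This is the mesh-based counterpart of the analytic dwell
#' geometry used by the virtual knee.
#'
#' @param femoral_mesh a [trimesh()] in the femoral component frame.
#' @param femur_pose [pose()] mapping the mesh into the (world) frame in
#'   which the tray frame is expressed.
#' @param tray a [tray_frame()].
#' @param split_ml medial-lateral coordinate of the sagittal split plane
#'   (mm, tray frame); vertices with `ml > split_ml` are medial.
#' @return a [condylar_lowpoints()].
#' @export
low_points <- function(femoral_mesh, femur_pose, tray, split_ml = 0) {
  stopifnot(inherits(femoral_mesh, "trimesh"), inherits(tray, "tray_frame"))
  pts <- pose_apply(femur_pose, femoral_mesh$vertices)
  tc <- tray_coords(tray, pts)
  med <- tc[, "ml"] > split_ml
  if (!any(med) || all(med))
    stop("empty condyle partition: no vertices on one side of the split plane")
  im <- which(med)[which.min(tc[med, "height"])]
  il <- which(!med)[which.min(tc[!med, "height"])]
  condylar_lowpoints(medial_ap = unname(tc[im, "ap"]),
                     lateral_ap = unname(tc[il, "ap"]),
                     medial_ml = unname(tc[im, "ml"]) - split_ml,
                     lateral_ml = unname(tc[il, "ml"]) - split_ml,
                     height_medial = unname(tc[im, "height"]),
                     height_lateral = unname(tc[il, "height"]))
}
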