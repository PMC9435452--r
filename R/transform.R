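#' Construct a rigid transform
#'
#' A proper rigid motion x -> R x + t. The rotation must be orthonormal with
#' determinant +1: reflections are deliberately not representable here,
#' mirroring is a separate operation ([mirror_mesh()]).
#'
#' @param rotation 3 x 3 orthonormal matrix, det = +1.
#' @param translation length-3 numeric vector, mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (length(translation) != 3L) stop("translation must have length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation has determinant != +1 (reflections are not rigid transforms)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: rotation %.3f deg, translation %.3f mm\n",
              rotation_angle_deg(x$rotation), sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param t a `rigid_transform`.
#' @return a `rigid_transform` with `t` applied then inverted = identity.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

#' Apply a rigid transform to a mesh
#'
#' Maps every vertex x -> R x + t; topology and colours are untouched and
#' derived normals rotate with the surface.
#'
#' @param mesh a `triangle_mesh`.
#' @param transform a `rigid_transform`.
#' @return the transformed `triangle_mesh`.
#' @export
apply_transform <- function(mesh, transform) {
  v <- mesh$vertices %*% t(transform$rotation)
  v <- sweep(v, 2L, transform$translation, "+")
  triangle_mesh(v, mesh$faces, mesh$colors)
}

#' Apply a rigid transform to a point matrix
#'
#' @param points n x 3 numeric matrix.
#' @param transform a `rigid_transform`.
#' @return n x 3 matrix of transformed points.
#' @export
transform_points <- function(points, transform) {
  sweep(points %*% t(transform$rotation), 2L, transform$translation, "+")
}

#' Rotation angle of a rigid transform, degrees
#'
#' @param rotation 3 x 3 rotation matrix.
#' @return rotation angle about the screw axis in degrees.
#' @export
rotation_angle_deg <- function(rotation) {
  c_ang <- (sum(diag(rotation)) - 1) / 2
  acos(min(1, max(-1, c_ang))) * 180 / pi
}

#' Least-squares rigid fit between paired point sets (Kabsch)
#'
#' Finds the proper rigid transform minimising the sum of squared distances
#' between `transform(source)` and `target` over paired rows. The SVD sign
#' correction excludes reflections, so the result is always a proper
#' rotation even for near-planar configurations.
#'
#' @param source,target n x 3 matrices of paired points (n >= 3).
#' @return a `rigid_transform` mapping source points onto target points.
#' @export
kabsch <- function(source, target) {
  if (nrow(source) != nrow(target)) stop("point sets must be paired")
  if (nrow(source) < 3L) stop("at least 3 point pairs are required")
  cs <- colMeans(source)
  ct <- colMeans(target)
  H <- crossprod(sweep(source, 2L, cs), sweep(target, 2L, ct))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.numeric(R %*% cs))
}

# Build a rotation matrix from per-axis angles in degrees (XYZ order).
rotation_xyz_deg <- function(ax, ay, az) {
  cx <- cos(ax * pi / 180); sx <- sin(ax * pi / 180)
  cy <- cos(ay * pi / 180); sy <- sin(ay * pi / 180)
  cz <- cos(az * pi / 180); sz <- sin(az * pi / 180)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Draw a random rigid transform
#'
#' Rotation angles per axis are uniform within `max_angle_deg` and the
#' translation uniform within a cube of half-width `max_translation_mm`.
#' Useful for pose-jitter simulation and for registration test cases.
#'
#' @param max_angle_deg maximum per-axis rotation, degrees.
#' @param max_translation_mm maximum per-axis translation, mm.
#' @return a `rigid_transform`.
#' @export
random_rigid_transform <- function(max_angle_deg = 5, max_translation_mm = 10) {
  ang <- stats::runif(3, -max_angle_deg, max_angle_deg)
  tr <- stats::runif(3, -max_translation_mm, max_translation_mm)
  rigid_transform(rotation_xyz_deg(ang[1], ang[2], ang[3]), tr)
}
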