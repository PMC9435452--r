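#' Construct an oriented plane
#'
#' The plane is the point set \{x : normal . x = offset\}, with a unit
#' normal. Used for the midsagittal reflection plane and for halfspace ROIs.
#'
#' @param normal length-3 vector; normalised internally.
#' @param offset scalar, mm.
#' @return an object of class `plane3d`.
#' @export
plane3d <- function(normal, offset = 0) {
  normal <- as.numeric(normal)
  if (length(normal) != 3L) stop("normal must have length 3")
  len <- sqrt(sum(normal^2))
  if (len < 1e-12) stop("plane normal must be non-zero")
  structure(list(normal = normal / len, offset = offset / len),
            class = "plane3d")
}

#' @export
print.plane3d <- function(x, ...) {
  cat(sprintf("plane3d: normal (%.4f, %.4f, %.4f), offset %.4f mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

#' Reflect points across a plane
#'
#' Householder reflection x -> x - 2 (normal . x - offset) normal.
#'
#' @param points n x 3 matrix.
#' @param plane a `plane3d`.
#' @return n x 3 matrix of reflected points.
#' @export
reflect_points <- function(points, plane) {
  s <- as.numeric(points %*% plane$normal) - plane$offset
  points - 2 * outer(s, plane$normal)
}

#' Mirror a mesh across a plane
#'
#' Reflects every vertex across the plane and reverses the face winding so
#' that derived normals stay outward. The result is the "mirrored 3D
#' photograph": comparing it against the original turns one capture into
#' its own left-right control, which is what removes growth between visits
#' as a confound.
#'
#' @param mesh a `triangle_mesh`.
#' @param plane a `plane3d`.
#' @return the mirrored `triangle_mesh`.
#' @export
mirror_mesh <- function(mesh, plane) {
  v <- reflect_points(mesh$vertices, plane)
  f <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  triangle_mesh(v, f, mesh$colors)
}

# Least-squares plane through >= 3 points (smallest singular direction).
.fit_plane <- function(points) {
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2L, ctr))
  if (sv$d[2L] < 1e-9 * max(sv$d[1L], 1))
    stop("degenerate landmarks: points are collinear")
  n <- sv$v[, 3L]
  plane3d(n, sum(n * ctr))
}

# Deterministic orientation: flip so the largest-magnitude component of the
# normal is positive (the two orientations describe the same plane; a fixed
# rule keeps runs reproducible).
.orient_plane <- function(plane) {
  k <- which.max(abs(plane$normal))
  if (plane$normal[k] < 0) plane3d(-plane$normal, -plane$offset) else plane
}

#' Estimate the midsagittal plane of a facial mesh
#'
#' With midline landmarks (>= 3, e.g. nasion / subnasale / pogonion) the
#' plane is their least-squares fit. Without landmarks the plane is found
#' automatically: the three principal planes of the vertex cloud are scored
#' by how well the reflected surface matches the original, the best one
#' seeds a symmetry refinement (reflect, register the reflection back onto
#' the original with ICP, extract the plane of the composed improper
#' transform, iterate to a fixed point).
#'
#' @param mesh a `triangle_mesh`.
#' @param landmarks optional k x 3 matrix of midline landmark coordinates.
#' @param icp an `icp_params` used by the symmetry refinement.
#' @param refine_iterations maximum symmetry-refinement sweeps.
#' @param tol convergence tolerance on the plane parameters.
#' @return a `plane3d`.
#' @export
estimate_midsagittal_plane <- function(mesh, landmarks = NULL,
                                       icp = icp_params(max_iterations = 30,
                                                        sample_size = 2000),
                                       refine_iterations = 20, tol = 1e-9) {
  if (!is.null(landmarks)) {
    landmarks <- as.matrix(landmarks)
    if (nrow(landmarks) < 3L) stop("at least 3 midline landmarks are required")
    return(.orient_plane(.fit_plane(landmarks)))
  }
  v <- mesh$vertices
  if (nrow(v) < 3L) stop("mesh needs at least 3 vertices")
  ctr <- colMeans(v)
  ev <- eigen(stats::cov(v), symmetric = TRUE)

  # score the three principal planes by reflected-sample misfit
  tree <- .bvh_build(v, mesh$faces)
  idx <- round(seq(1L, nrow(v), length.out = min(500L, nrow(v))))
  scores <- vapply(1:3, function(k) {
    p <- plane3d(ev$vectors[, k], sum(ev$vectors[, k] * ctr))
    refl <- reflect_points(v[idx, , drop = FALSE], p)
    mean(.bvh_closest(tree, refl)$distance)
  }, numeric(1))
  k <- which.min(scores)
  plane <- .orient_plane(plane3d(ev$vectors[, k], sum(ev$vectors[, k] * ctr)))

  for (it in seq_len(refine_iterations)) {
    mirrored <- mirror_mesh(mesh, plane)
    fit <- icp_align(mirrored, mesh, init = rigid_transform(), params = icp,
                     target_tree = tree)
    plane_new <- .compose_reflection(fit$transform, plane)
    delta <- max(abs(plane_new$normal - plane$normal),
                 abs(plane_new$offset - plane$offset) /
                   max(1, abs(plane$offset)))
    plane <- plane_new
    if (delta < tol) break
  }
  plane
}

# Compose rigid transform T with the reflection H across `plane` and return
# the mirror plane of the nearest pure reflection to T o H. The linear part
# A = R (I - 2 n n') is improper orthogonal and always has a real -1
# eigenvector: that direction is the refined normal, and for a pure
# reflection the translation is 2 d n, giving the refined offset.
.compose_reflection <- function(transform, plane) {
  n <- plane$normal
  H <- diag(3) - 2 * tcrossprod(n)
  A <- transform$rotation %*% H
  tG <- as.numeric(transform$rotation %*% (2 * plane$offset * n)) +
    transform$translation
  eg <- eigen(A)
  k <- which.min(abs(eg$values + 1))
  n_new <- Re(eg$vectors[, k])
  n_new <- n_new / sqrt(sum(n_new^2))
  if (sum(n_new * n) < 0) n_new <- -n_new
  .orient_plane(plane3d(n_new, sum(n_new * tG) / 2))
}
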