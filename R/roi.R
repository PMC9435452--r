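#' Declare a region of interest
#'
#' The capture protocol keeps confounding areas such as the neck out of the
#' analysed surface. Interactive trimming is replaced here by a declarative
#' ROI so every run is reproducible: `whole` (no cropping), `halfspace`
#' (keep vertices with `normal . x >= offset`), `sphere` (keep vertices
#' within `radius` of `center`), or `landmark_polygon` (keep vertices whose
#' projection onto the best-fit plane of an ordered landmark loop falls
#' inside that polygon).
#'
#' @param kind one of `"whole"`, `"halfspace"`, `"sphere"`,
#'   `"landmark_polygon"`.
#' @param plane a `plane3d` (halfspace kind).
#' @param center,radius sphere centre (length-3, mm) and radius (mm).
#' @param loop ordered k x 3 matrix of landmark coordinates (polygon kind).
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(kind = c("whole", "halfspace", "sphere",
                              "landmark_polygon"),
                     plane = NULL, center = NULL, radius = NULL,
                     loop = NULL) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    whole = list(kind = kind),
    halfspace = {
      if (!inherits(plane, "plane3d")) stop("halfspace ROI needs a plane3d")
      list(kind = kind, plane = plane)
    },
    sphere = {
      if (is.null(center) || length(center) != 3L)
        stop("sphere ROI needs a length-3 center")
      if (is.null(radius) || radius <= 0) stop("sphere ROI needs radius > 0")
      list(kind = kind, center = as.numeric(center), radius = radius)
    },
    landmark_polygon = {
      loop <- as.matrix(loop)
      if (is.null(loop) || nrow(loop) < 3L || ncol(loop) != 3L)
        stop("landmark_polygon ROI needs an ordered k x 3 loop, k >= 3")
      list(kind = kind, loop = loop)
    })
  structure(spec, class = "roi_spec")
}

.roi_keep <- function(vertices, roi) {
  switch(roi$kind,
    whole = rep(TRUE, nrow(vertices)),
    halfspace = as.numeric(vertices %*% roi$plane$normal) >= roi$plane$offset,
    sphere = sqrt(rowSums(sweep(vertices, 2L, roi$center)^2)) <= roi$radius,
    landmark_polygon = {
      # project onto the loop's best-fit plane, test 2D point-in-polygon
      ctr <- colMeans(roi$loop)
      sv <- svd(sweep(roi$loop, 2L, ctr))
      basis <- sv$v[, 1:2, drop = FALSE]
      poly <- sweep(roi$loop, 2L, ctr) %*% basis
      pts <- sweep(vertices, 2L, ctr) %*% basis
      .point_in_polygon(pts, poly)
    })
}

# Even-odd ray-casting point-in-polygon test, vectorised over points.
.point_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > pts[, 2L]) != (yj > pts[, 2L])) &
      (pts[, 1L] < (xj - xi) * (pts[, 2L] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Crop a mesh to a region of interest
#'
#' Keeps the vertices satisfying the ROI predicate and the faces whose
#' three vertices are all kept (conservative rule: no sliver triangles are
#' created at the boundary). Indices are re-compacted; the input mesh is
#' untouched.
#'
#' @param mesh a `triangle_mesh`.
#' @param roi an `roi_spec`.
#' @return the cropped `triangle_mesh`.
#' @export
crop_roi <- function(mesh, roi) {
  if (!inherits(roi, "roi_spec")) stop("roi must be an roi_spec")
  keep <- .roi_keep(mesh$vertices, roi)
  if (!any(keep)) stop("ROI excludes all vertices")
  new_idx <- cumsum(keep)
  fkeep <- keep[mesh$faces[, 1L]] & keep[mesh$faces[, 2L]] &
    keep[mesh$faces[, 3L]]
  faces <- matrix(new_idx[mesh$faces[fkeep, , drop = FALSE]], ncol = 3L)
  triangle_mesh(mesh$vertices[keep, , drop = FALSE], faces,
                if (!is.null(mesh$colors)) mesh$colors[keep, , drop = FALSE])
}
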