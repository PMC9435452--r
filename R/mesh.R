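#' Construct a triangle surface mesh
#'
#' The basic container of the package: an open triangulated shell in
#' millimetres, the in-silico counterpart of a stereophotogrammetric facial
#' capture. Vertices are stored as an n x 3 numeric matrix in a right-handed
#' coordinate frame; faces as an m x 3 integer matrix of 1-based vertex
#' indices with counter-clockwise winding seen from outside.
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param faces integer matrix (m x 3), 1-based vertex indices.
#' @param colors optional integer matrix (n x 3) of per-vertex RGB in 0..255.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, colors = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) == 0L) faces <- matrix(integer(0), 0L, 3L)
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    storage.mode(colors) <- "integer"
    dimnames(colors) <- NULL
    if (nrow(colors) != nrow(vertices) || ncol(colors) != 3L)
      stop("colors must be an n x 3 matrix matching the vertices")
    if (any(colors < 0L | colors > 255L)) stop("colors must lie in 0..255")
  }
  mesh <- structure(list(vertices = vertices, faces = faces, colors = colors),
                    class = "triangle_mesh")
  validate_mesh(mesh)
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("triangle_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$colors)) ", vertex colours" else ""))
  cat(sprintf("  bounding box (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

validate_mesh <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  if (nrow(f) > 0L) {
    if (any(f < 1L) || any(f > nv))
      stop("face index out of range [1, n_vertices]")
    degen <- f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]
    if (any(degen))
      stop(sprintf("degenerate face (repeated vertex index) at face %d",
                   which(degen)[1L]))
  }
  if (anyNA(mesh$vertices)) stop("vertices contain NA")
  invisible(TRUE)
}

#' Per-face unit normals and areas
#'
#' Normals follow the face winding (counter-clockwise = outward).
#' Zero-area faces get a zero normal rather than NaN.
#'
#' @param mesh a `triangle_mesh`.
#' @return list with `normals` (m x 3, unit rows) and `areas` (length m, mm^2).
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(cr^2))
  n <- cr / ifelse(len > 0, len, 1)
  list(normals = n, areas = len / 2)
}

#' Per-vertex unit normals
#'
#' Area-weighted average of incident face normals, normalised to unit
#' length; the orientation is inherited from the face winding, so a mesh
#' with consistent outward winding gets outward vertex normals.
#'
#' @param mesh a `triangle_mesh`.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  w <- fn$normals * fn$areas    # area-weighted (cross product magnitude)
  n <- matrix(0, nrow(mesh$vertices), 3L)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    for (j in 1:3) {
      acc <- rowsum(w[, j], idx)
      rows <- as.integer(rownames(acc))
      n[rows, j] <- n[rows, j] + acc[, 1L]
    }
  }
  len <- sqrt(rowSums(n^2))
  n / ifelse(len > 0, len, 1)
}

#' Per-vertex area weights (one third of incident face area)
#'
#' Used for uniform-by-area sampling of surface points.
#'
#' @param mesh a `triangle_mesh`.
#' @return numeric vector of length n_vertices, mm^2.
#' @export
vertex_areas <- function(mesh) {
  ar <- face_normals(mesh)$areas / 3
  a <- numeric(nrow(mesh$vertices))
  for (k in 1:3) {
    acc <- rowsum(ar, mesh$faces[, k])
    rows <- as.integer(rownames(acc))
    a[rows] <- a[rows] + acc[, 1L]
  }
  a
}

# Signed volume of the shell against the plane z = z0 (prism rule over the
# projected faces). Used to check that a simulated atrophy removes volume.
shell_volume <- function(mesh, z0 = min(mesh$vertices[, 3L])) {
  v <- mesh$vertices
  f <- mesh$faces
  x1 <- v[f[, 1L], 1L]; y1 <- v[f[, 1L], 2L]; z1 <- v[f[, 1L], 3L]
  x2 <- v[f[, 2L], 1L]; y2 <- v[f[, 2L], 2L]; z2 <- v[f[, 2L], 3L]
  x3 <- v[f[, 3L], 1L]; y3 <- v[f[, 3L], 2L]; z3 <- v[f[, 3L], 3L]
  area_xy <- ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
  sum(area_xy * ((z1 + z2 + z3) / 3 - z0))
}
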