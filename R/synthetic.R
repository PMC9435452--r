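#' Parameters of the synthetic base face
#'
#' The base surface is a paraboloid-like open shell over an elliptical
#' domain with smooth superposed features (a midline nose ridge, paired
#' brow and cheek bumps, a chin bump). It is exactly mirror-symmetric about
#' the plane x = 0 by construction: vertices are generated in +-x pairs and
#' every height term depends on x only through x^2, so the symmetry holds
#' to the last bit. Dimensions are half-axes in mm of a roughly
#' adolescent-sized face.
#'
#' @param n_vertices target vertex count (>= 100); the realised count
#'   depends on the elliptical trimming of the vertex grid.
#' @param width,height,depth half-axes of the shell, mm.
#' @param nose_amp,brow_amp,cheek_amp,chin_amp feature heights, mm.
#' @param seed RNG seed (the base face itself is deterministic; the seed is
#'   carried along for downstream noise stages).
#' @return an object of class `face_params`.
#' @export
face_params <- function(n_vertices = 20000, width = 60, height = 90,
                        depth = 35, nose_amp = 12, brow_amp = 4,
                        cheek_amp = 5, chin_amp = 5, seed = 1L) {
  if (n_vertices < 100) stop("n_vertices must be >= 100")
  if (any(c(width, height, depth) <= 0)) stop("face dimensions must be positive")
  structure(list(n_vertices = n_vertices, width = width, height = height,
                 depth = depth, nose_amp = nose_amp, brow_amp = brow_amp,
                 cheek_amp = cheek_amp, chin_amp = chin_amp,
                 seed = as.integer(seed)),
            class = "face_params")
}

# Smooth anisotropic Gaussian bump in mm coordinates; symmetric pairs are
# expressed through x^2 so reflection symmetry is exact in floating point.
.bump <- function(x, y, amp, cx, cy, sx, sy) {
  amp * exp(-(((x - cx)^2) / (2 * sx^2) + ((y - cy)^2) / (2 * sy^2)))
}
.bump_pair <- function(x, y, amp, cx, cy, sx, sy) {
  .bump(x, y, amp, cx, cy, sx, sy) + .bump(x, y, amp, -cx, cy, sx, sy)
}

.face_height <- function(x, y, p) {
  u2 <- (x / p$width)^2 + (y / p$height)^2
  z <- p$depth * (1 - u2)
  z <- z + .bump(x, y, p$nose_amp, 0, -5, 9, 22)          # nose ridge
  z <- z + .bump_pair(x, y, p$brow_amp, 24, 32, 13, 9)    # brow arches
  z <- z + .bump_pair(x, y, p$cheek_amp, 32, -12, 14, 16) # cheeks
  z <- z + .bump(x, y, p$chin_amp, 0, -72, 14, 12)        # chin
  z
}

#' Generate the symmetric base face
#'
#' @param params a `face_params`.
#' @return a `triangle_mesh`: an open shell of about `n_vertices` vertices,
#'   exactly mirror-symmetric about x = 0, with outward (+z biased) face
#'   winding. Deterministic: the same parameters always give a bitwise
#'   identical mesh.
#' @export
generate_base_face <- function(params = face_params()) {
  p <- params
  # grid sized so that the elliptically trimmed count is ~ n_vertices
  n_grid <- p$n_vertices * 4 / pi
  nx <- max(5L, round(sqrt(n_grid * p$width / p$height)))
  m <- max(2L, floor((nx - 1L) / 2L))
  ny <- max(5L, round(n_grid / (2L * m + 1L)))
  half <- (seq_len(m) / m) * p$width
  xs <- c(-rev(half), 0, half)        # exact +-x pairs, x = 0 on the midline
  nx <- length(xs)
  ys <- seq(-p$height, p$height, length.out = ny)

  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  keep <- (X / p$width)^2 + (Y / p$height)^2 <= 1
  if (sum(keep) < 100)
    stop("n_vertices too small to mesh the face features")

  idx <- matrix(0L, nx, ny)
  idx[keep] <- seq_len(sum(keep))
  x <- X[keep]; y <- Y[keep]
  z <- .face_height(x, y, p)

  # two triangles per fully kept grid cell, counter-clockwise from +z
  a <- idx[-nx, -ny]; b <- idx[-1L, -ny]; c3 <- idx[-nx, -1L]; d <- idx[-1L, -1L]
  full <- a > 0L & b > 0L & c3 > 0L & d > 0L
  faces <- rbind(cbind(a[full], b[full], d[full]),
                 cbind(a[full], d[full], c3[full]))
  # drop grid vertices not referenced by any face (isolated ellipse tips)
  used <- sort(unique(as.vector(faces)))
  remap <- integer(length(x))
  remap[used] <- seq_along(used)
  triangle_mesh(cbind(x, y, z)[used, , drop = FALSE],
                matrix(remap[faces], ncol = 3L))
}

#' Describe a simulated atrophic lesion
#'
#' Progressive hemifacial atrophy presents as one-sided tissue loss; the
#' simulated lesion displaces vertices inward along their normals with a
#' smooth radial falloff of compact support (zero beyond 3 radii), so the
#' contralateral side away from the support is untouched.
#'
#' @param center length-3 point on the surface, strictly off the x = 0
#'   symmetry plane.
#' @param radius falloff scale, mm.
#' @param depth peak inward displacement, mm (>= 0).
#' @param profile `"gaussian"` (exp(-u^2/2), truncated at u = 3) or
#'   `"cosine"` (raised cosine reaching 0 at u = 3).
#' @return an object of class `atrophy_field`.
#' @export
atrophy_field <- function(center, radius = 15, depth = 0,
                          profile = c("gaussian", "cosine")) {
  profile <- match.arg(profile)
  center <- as.numeric(center)
  if (length(center) != 3L) stop("center must have length 3")
  if (center[1L] == 0) stop("lesion center must lie strictly on one side of x = 0")
  if (radius <= 0) stop("radius must be > 0")
  if (depth < 0) stop("depth must be >= 0")
  structure(list(center = center, radius = radius, depth = depth,
                 profile = profile), class = "atrophy_field")
}

.falloff <- function(u, profile) {
  w <- switch(profile,
              gaussian = exp(-u^2 / 2),
              cosine = (1 + cos(pi * pmin(u, 3) / 3)) / 2)
  w[u >= 3] <- 0
  w
}

#' Apply an atrophic lesion to a mesh
#'
#' Each vertex moves inward along its own normal by
#' `depth * w(|v - center| / radius)`; topology is unchanged. With
#' `depth = 0` the mesh is returned bitwise unchanged.
#'
#' @param mesh a `triangle_mesh`.
#' @param field an `atrophy_field`.
#' @return the deformed `triangle_mesh`.
#' @export
apply_atrophy <- function(mesh, field) {
  if (field$depth == 0) return(mesh)
  d <- sqrt(rowSums(sweep(mesh$vertices, 2L, field$center)^2))
  w <- .falloff(d / field$radius, field$profile)
  v <- mesh$vertices - field$depth * w * vertex_normals(mesh)
  triangle_mesh(v, mesh$faces, mesh$colors)
}

#' Parameters of a longitudinal capture series
#'
#' Encodes the confounds a growing patient brings to repeated captures:
#' global craniofacial growth (a scale factor per visit), a progressing
#' lesion (a depth per visit), per-vertex acquisition noise along the
#' normals (scanner depth error; default 0.3 mm, the reproducibility scale
#' of clinical stereophotogrammetry), and a random rigid pose per capture.
#'
#' @param timepoints follow-up offsets in months, strictly increasing.
#' @param growth_scale cumulative global scale factor per timepoint
#'   relative to baseline (dimensionless, > 0).
#' @param atrophy_depth lesion depth per timepoint, mm.
#' @param noise_sigma std of Gaussian vertex noise along normals, mm.
#' @param pose_jitter_deg,pose_jitter_mm max random rigid perturbation per
#'   capture.
#' @param seed RNG seed; every stage derives its own sub-seed from it.
#' @return an object of class `series_params`.
#' @export
series_params <- function(timepoints = c(0, 12, 24),
                          growth_scale = rep(1, length(timepoints)),
                          atrophy_depth = rep(0, length(timepoints)),
                          noise_sigma = 0.3,
                          pose_jitter_deg = 5, pose_jitter_mm = 10,
                          seed = 1L) {
  if (length(growth_scale) != length(timepoints) ||
      length(atrophy_depth) != length(timepoints))
    stop("growth_scale and atrophy_depth must match timepoints in length")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  if (any(growth_scale <= 0)) stop("growth_scale must be > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(timepoints = timepoints, growth_scale = growth_scale,
                 atrophy_depth = atrophy_depth, noise_sigma = noise_sigma,
                 pose_jitter_deg = pose_jitter_deg,
                 pose_jitter_mm = pose_jitter_mm, seed = as.integer(seed)),
            class = "series_params")
}

# Fold a stage label into the run seed: reproducible, stage-independent
# streams from one user-facing seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Simulate a longitudinal capture series
#'
#' For each timepoint the base face is scaled by the cumulative growth
#' factor (about the origin, which lies on the symmetry plane, so growth
#' commutes exactly with mirroring), deformed by the scheduled lesion depth
#' (the lesion centre and radius scale with growth so the defect follows
#' the anatomy), perturbed by Gaussian noise along the vertex normals, and
#' finally moved by a random rigid pose. Stages with zero magnitude are
#' skipped, so a null schedule reproduces the base face bitwise.
#'
#' @param base a `face_params`.
#' @param series a `series_params`.
#' @param atrophy an `atrophy_field` giving the lesion geometry; its
#'   `depth` is overridden by the per-timepoint schedule. `NULL` when every
#'   scheduled depth is zero.
#' @return a list of class `face_series`; one entry per timepoint with
#'   `timepoint_months`, `mesh` and the applied ground `truth` (depth,
#'   scale, pose) for test use.
#' @export
simulate_series <- function(base = face_params(), series = series_params(),
                            atrophy = NULL) {
  if (any(series$atrophy_depth > 0) && is.null(atrophy))
    stop("an atrophy_field is required when the depth schedule is non-zero")
  mesh0 <- generate_base_face(base)
  out <- vector("list", length(series$timepoints))
  for (k in seq_along(series$timepoints)) {
    mesh <- mesh0
    s <- series$growth_scale[k]
    if (s != 1)
      mesh <- triangle_mesh(mesh$vertices * s, mesh$faces)
    depth_k <- series$atrophy_depth[k]
    if (depth_k > 0) {
      fld <- atrophy_field(atrophy$center * s, atrophy$radius * s,
                           depth_k, atrophy$profile)
      mesh <- apply_atrophy(mesh, fld)
    }
    if (series$noise_sigma > 0) {
      nrm <- vertex_normals(mesh)
      eps <- with_seed(derive_seed(series$seed, sprintf("noise_tp%d", k)),
                       stats::rnorm(nrow(mesh$vertices), 0, series$noise_sigma))
      mesh <- triangle_mesh(mesh$vertices + eps * nrm, mesh$faces)
    }
    pose <- rigid_transform()
    if (series$pose_jitter_deg > 0 || series$pose_jitter_mm > 0) {
      pose <- with_seed(derive_seed(series$seed, sprintf("pose_tp%d", k)),
                        random_rigid_transform(series$pose_jitter_deg,
                                               series$pose_jitter_mm))
      mesh <- apply_transform(mesh, pose)
    }
    out[[k]] <- list(timepoint_months = series$timepoints[k], mesh = mesh,
                     truth = list(depth_mm = depth_k, scale = s, pose = pose))
  }
  structure(out, class = "face_series")
}
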