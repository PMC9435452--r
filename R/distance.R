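#' Signed inter-surface distance map
#'
#' For every vertex of the original mesh, the closest point on the
#' registered mirrored surface is found by a true point-to-triangle query.
#' The absolute distance is the Euclidean length of that gap; the sign is
#' positive where the mirrored surface lies outside the original (the
#' contralateral side carries more volume there — rendered green), negative
#' where it lies inside (local volume loss — rendered red). Vertices at
#' zero distance take sign +1 by convention.
#'
#' @param original the original `triangle_mesh` (the ROI-cropped capture).
#' @param mirrored_aligned the mirrored mesh, already registered into the
#'   original's frame.
#' @param symmetric average the forward absolute distances with the
#'   per-vertex distances measured back from the mirrored vertices to the
#'   original surface (the mirrored mesh shares the original's vertex
#'   numbering, so the two maps align). The signed map always comes from
#'   the original-to-mirror direction. Default off: a single well-defined
#'   per-vertex map is what gets coloured.
#' @return list of class `distance_map`: `signed` and `absolute`
#'   per-vertex distances (mm) and the source `mesh`.
#' @export
signed_distance_map <- function(original, mirrored_aligned,
                                symmetric = FALSE) {
  if (nrow(original$vertices) == 0L || nrow(mirrored_aligned$vertices) == 0L)
    stop("signed_distance_map: empty mesh")
  cp <- closest_points(original$vertices, mirrored_aligned)
  gap <- cp$point - original$vertices
  sgn <- ifelse(rowSums(gap * vertex_normals(original)) >= 0, 1, -1)
  absolute <- cp$distance
  signed <- sgn * absolute
  if (symmetric &&
      nrow(mirrored_aligned$vertices) == nrow(original$vertices)) {
    back <- closest_points(mirrored_aligned$vertices, original)
    absolute <- (absolute + back$distance) / 2
    signed <- sgn * absolute
  }
  structure(list(signed = signed, absolute = absolute, mesh = original),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("distance_map: %d vertices, mean |d| %.3f mm, max |d| %.3f mm\n",
              length(x$signed), mean(x$absolute), max(x$absolute)))
  invisible(x)
}

#' Summarise a distance map into per-timepoint asymmetry statistics
#'
#' T_mean is the mean absolute (Euclidean) distance in mm and T_sd its
#' population standard deviation (divide by n). `pct_within[c]` is the
#' unweighted percentage of surface points whose absolute distance is <= c
#' (inclusive), for the requested cut-offs; 100 means the whole analysed
#' surface lies within the band. Optional area weighting replaces the
#' vertex count by the per-vertex Voronoi-style area share.
#'
#' @param dmap a `distance_map`.
#' @param cutoffs positive cut-off distances in mm, ascending
#'   (default 1, 2, 5).
#' @param timepoint_months follow-up offset carried into the report.
#' @param area_weighted weight vertices by incident surface area.
#' @return an object of class `asymmetry_report` with fields `t_mean_mm`,
#'   `t_sd_mm`, `pct_within` (named by cut-off), `cutoffs`,
#'   `timepoint_months`, `n_vertices`.
#' @export
summarize_asymmetry <- function(dmap, cutoffs = c(1, 2, 5),
                                timepoint_months = 0,
                                area_weighted = FALSE) {
  if (length(dmap$absolute) == 0L) stop("summarize_asymmetry: empty distance map")
  if (any(cutoffs <= 0) || is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be positive and strictly ascending")
  a <- dmap$absolute
  w <- if (area_weighted) {
    va <- vertex_areas(dmap$mesh)
    if (length(va) != length(a)) rep(1, length(a)) else va / sum(va)
  } else rep(1 / length(a), length(a))
  pct <- vapply(cutoffs, function(ct) 100 * sum(w[a <= ct]), numeric(1))
  names(pct) <- sprintf("%g", cutoffs)
  structure(list(t_mean_mm = sum(w * a),
                 t_sd_mm = sqrt(sum(w * (a - sum(w * a))^2)),
                 pct_within = pct, cutoffs = cutoffs,
                 timepoint_months = timepoint_months,
                 n_vertices = length(a)),
            class = "asymmetry_report")
}

#' @export
print.asymmetry_report <- function(x, ...) {
  cat(sprintf("asymmetry_report (t = %g months): T_mean %.2f mm (sd %.2f)\n",
              x$timepoint_months, x$t_mean_mm, x$t_sd_mm))
  for (i in seq_along(x$cutoffs))
    cat(sprintf("  within %g mm: %.1f%%\n", x$cutoffs[i], x$pct_within[i]))
  invisible(x)
}

#' Colour a mesh by its signed distance map
#'
#' Diverging scale over a symmetric range: -range maps to pure red (local
#' volume loss), 0 to neutral white, +range to pure green (volume
#' increase); values beyond the range are clipped. The result can be
#' written as a colour PLY with [write_mesh()].
#'
#' @param dmap a `distance_map`.
#' @param range_mm half-width of the colour range, mm (> 0).
#' @return the source `triangle_mesh` with per-vertex colours attached.
#' @export
export_colour_map <- function(dmap, range_mm = 5) {
  if (range_mm <= 0) stop("range_mm must be > 0")
  s <- pmin(1, pmax(-1, dmap$signed / range_mm))
  # white -> green for positive distances, white -> red for negative
  col <- cbind(ifelse(s >= 0, round(255 * (1 - s)), 255),
               ifelse(s >= 0, 255, round(255 * (1 + s))),
               round(255 * (1 - abs(s))))
  triangle_mesh(dmap$mesh$vertices, dmap$mesh$faces, col)
}
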