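#' Configuration of a single-timepoint asymmetry analysis
#'
#' Bundles every tunable of the composed pipeline; nothing is hard-coded
#' in the stages, so two runs with equal configs are bitwise reproducible.
#'
#' @param roi an `roi_spec`; default `whole` (no cropping).
#' @param landmarks optional k x 3 midline landmark matrix used for the
#'   midsagittal plane (and skipping the automatic estimate).
#' @param icp an `icp_params` for the fine alignment.
#' @param plane_icp an `icp_params` for the symmetry refinement of the
#'   midsagittal plane (smaller sample, fewer iterations).
#' @param refine_plane refine the automatic plane by symmetry registration.
#' @param cutoffs report cut-offs, mm.
#' @param colour_range_mm symmetric colour range of the exported map, mm.
#' @param area_weighted area-weight the summary statistics.
#' @param symmetric_distance use the symmetrised absolute distance map.
#' @param seed seed fanned out to the seeded stages.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(roi = roi_spec("whole"), landmarks = NULL,
                            icp = icp_params(),
                            plane_icp = icp_params(max_iterations = 30,
                                                   sample_size = 2000),
                            refine_plane = TRUE,
                            cutoffs = c(1, 2, 5), colour_range_mm = 5,
                            area_weighted = FALSE,
                            symmetric_distance = FALSE, seed = 1L) {
  icp$seed <- derive_seed(seed, "icp")
  plane_icp$seed <- derive_seed(seed, "plane_icp")
  structure(list(roi = roi, landmarks = landmarks, icp = icp,
                 plane_icp = plane_icp, refine_plane = refine_plane,
                 cutoffs = cutoffs, colour_range_mm = colour_range_mm,
                 area_weighted = area_weighted,
                 symmetric_distance = symmetric_distance,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Analyse the asymmetry of one facial capture
#'
#' The composed pipeline: crop to the ROI, estimate the midsagittal plane,
#' mirror, rough-align the mirror onto the original, fine-align with ICP,
#' compute the signed distance map, and summarise. Because the comparison
#' is a capture against its own mirror image, growth between visits cannot
#' masquerade as asymmetry, and the whole result is invariant (to
#' numerical tolerance) under rigid motion of the input.
#'
#' @param mesh a `triangle_mesh` (one capture).
#' @param config an `analysis_config`.
#' @param timepoint_months follow-up offset recorded in the report.
#' @return list of class `asymmetry_analysis`: `report`
#'   (an `asymmetry_report`), `dmap`, `coloured` (colour-mapped mesh),
#'   `mesh` (the analysed ROI mesh), `plane`, `rough`, `icp`
#'   (an `alignment_result`) and `log` (plain-list run record).
#' @export
analyze_timepoint <- function(mesh, config = analysis_config(),
                              timepoint_months = 0) {
  t0 <- proc.time()[["elapsed"]]
  roi_mesh <- .stage("crop_roi", crop_roi(mesh, config$roi))
  plane <- .stage("estimate_midsagittal_plane",
    if (!is.null(config$landmarks))
      estimate_midsagittal_plane(roi_mesh, landmarks = config$landmarks)
    else if (config$refine_plane)
      estimate_midsagittal_plane(roi_mesh, icp = config$plane_icp)
    else
      estimate_midsagittal_plane(roi_mesh, icp = config$plane_icp,
                                 refine_iterations = 0))
  mirrored <- .stage("mirror_mesh", mirror_mesh(roi_mesh, plane))
  rough <- .stage("rough_align", rough_align(mirrored, roi_mesh))
  fine <- .stage("icp_align",
                 icp_align(mirrored, roi_mesh, init = rough,
                           params = config$icp))
  mirrored_aligned <- apply_transform(mirrored, fine$transform)
  dmap <- .stage("signed_distance_map",
                 signed_distance_map(roi_mesh, mirrored_aligned,
                                     symmetric = config$symmetric_distance))
  report <- .stage("summarize_asymmetry",
                   summarize_asymmetry(dmap, cutoffs = config$cutoffs,
                                       timepoint_months = timepoint_months,
                                       area_weighted = config$area_weighted))
  coloured <- export_colour_map(dmap, config$colour_range_mm)
  log <- list(timepoint_months = timepoint_months,
              n_vertices_roi = nrow(roi_mesh$vertices),
              plane_normal = plane$normal, plane_offset_mm = plane$offset,
              icp_transform = .transform_matrix(fine$transform),
              icp_rms_mm = fine$rms_mm, icp_iterations = fine$n_iterations,
              icp_converged = fine$converged,
              icp_inlier_fraction = fine$inlier_fraction,
              seed = config$seed,
              elapsed_s = proc.time()[["elapsed"]] - t0)
  structure(list(report = report, dmap = dmap, coloured = coloured,
                 mesh = roi_mesh, plane = plane, rough = rough, icp = fine,
                 log = log),
            class = "asymmetry_analysis")
}

# 4 x 4 row-major homogeneous matrix of a rigid transform, for run logs.
.transform_matrix <- function(t) {
  m <- rbind(cbind(t$rotation, t$translation), c(0, 0, 0, 1))
  dimnames(m) <- NULL
  m
}

#' Build the longitudinal asymmetry table
#'
#' One row per timepoint in the clinical report layout: follow-up period in
#' months, T_mean in mm and the percentage of the surface within each
#' cut-off. Full-precision columns are kept alongside display columns
#' rounded the way the clinic reads them (T_mean to one decimal,
#' percentages to whole numbers).
#'
#' @param reports list of `asymmetry_report`, timepoints strictly
#'   increasing.
#' @return a `data.frame` with columns `timepoint_months`, `t_mean_mm`,
#'   `t_sd_mm`, one `pct_le_<c>mm` per cut-off, and display columns
#'   `t_mean_display` / `pct_le_<c>mm_display`.
#' @export
build_longitudinal_table <- function(reports) {
  if (length(reports) == 0L) stop("at least one report is required")
  if (inherits(reports, "asymmetry_report")) reports <- list(reports)
  tps <- vapply(reports, `[[`, numeric(1), "timepoint_months")
  if (anyDuplicated(tps)) stop("duplicate timepoints in reports")
  if (is.unsorted(tps, strictly = TRUE)) stop("timepoints must be strictly increasing")
  cutoffs <- reports[[1L]]$cutoffs
  tab <- data.frame(timepoint_months = tps,
                    t_mean_mm = vapply(reports, `[[`, numeric(1), "t_mean_mm"),
                    t_sd_mm = vapply(reports, `[[`, numeric(1), "t_sd_mm"))
  for (i in seq_along(cutoffs))
    tab[[sprintf("pct_le_%gmm", cutoffs[i])]] <-
      vapply(reports, function(r) unname(r$pct_within[i]), numeric(1))
  tab$t_mean_display <- sprintf("%.1f", tab$t_mean_mm)
  for (i in seq_along(cutoffs))
    tab[[sprintf("pct_le_%gmm_display", cutoffs[i])]] <-
      as.integer(round(tab[[sprintf("pct_le_%gmm", cutoffs[i])]]))
  tab
}

#' Render the longitudinal table as aligned text
#'
#' @param table output of [build_longitudinal_table()].
#' @return character vector of report lines.
#' @export
format_longitudinal_table <- function(table) {
  pct_cols <- grep("^pct_le_.*_display$", names(table), value = TRUE)
  head_pct <- sub("^pct_le_(.*)mm_display$", "T<=\\1mm (%)", pct_cols)
  header <- c("Follow-up (months)", "T_mean (mm)", head_pct)
  pct_mat <- vapply(pct_cols, function(cc) format(table[[cc]]),
                    character(nrow(table)))
  if (nrow(table) == 1L) pct_mat <- matrix(pct_mat, nrow = 1L)
  rows <- cbind(format(table$timepoint_months), table$t_mean_display, pct_mat)
  widths <- pmax(nchar(header), apply(nchar(rows), 2L, max))
  fmt_row <- function(x)
    paste(mapply(formatC, x, width = widths), collapse = "  ")
  c(fmt_row(header), apply(rows, 1L, fmt_row))
}
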