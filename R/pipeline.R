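#' Localize the vena contracta of a tracked Doppler sequence
#'
#' Runs the full estimation chain on an in-memory [frame_sequence()]:
#' cardiac-cycle gating of the peak-regurgitation frames, grayscale (B-mode)
#' removal and cool-flow suppression, maximum-intensity-projection
#' compounding, grayscale conversion, intensity thresholding,
#' largest-island selection, PCA alignment, width-profile minimum detection,
#' inverse PCA mapping, cone-surface lifting, and the calibration and
#' tracked-pose transforms into tracker space. When ground truth is supplied
#' the closest-distance error and the annulus-proximity outlier flag are
#' appended.
#'
#' The pose used for the tracker transform is that of the first selected peak
#' frame (the probe is held still over the short compounding window);
#' `pose_frame` overrides this with another original frame index.
#'
#' @param seq a [frame_sequence()].
#' @param calibration image-to-sensor rigid transform of the probe.
#' @param first_peak_index 1-based index of the first maximal-regurgitation
#'   frame, identified by the user scanning the first cycle.
#' @param frames_per_cycle how many consecutive frames to keep per cycle.
#' @param threshold binary segmentation intensity (default 150; use 130 for
#'   small/infant-valve flows).
#' @param gray_tol channel-spread tolerance of the grayscale filter.
#' @param interior_fraction end-exclusion fraction of the width-profile search.
#' @param ground_truth optional [ground_truth()] for validation.
#' @param pose_frame optional original frame index whose pose to use.
#' @param cool_suppression set `FALSE` to skip blue-dominant suppression
#'   (debugging only).
#' @return an object of class `"vc_localization"`; see [print.vc_localization()],
#'   [summary.vc_localization()], [coef.vc_localization()],
#'   [plot.vc_localization()]. Key fields: `vcw_px`, `vcw_mm`, `vc_px`,
#'   `vc_image_mm`, `vc_tracker_mm`, `frame_index`, `validation`.
#' @examples
#' params <- jet_scene_params(seed = 7)
#' meta <- acquisition_meta(15, 60, 30, 0.2, c(20, 100))
#' ds <- generate_dataset(params, meta, n_seconds = 5)
#' fit <- locate_vc(ds$sequence, ds$calibration, ds$first_peak_index, 3,
#'                  ground_truth = ds$ground_truth)
#' fit
#' @export
locate_vc <- function(seq, calibration, first_peak_index, frames_per_cycle,
                      threshold = 150, gray_tol = 20,
                      interior_fraction = 0.1, ground_truth = NULL,
                      pose_frame = NULL, cool_suppression = TRUE) {
  stopifnot(inherits(seq, "frame_sequence"))
  calibration <- rigid_transform(calibration)
  peak <- select_peak_frames(seq, first_peak_index, frames_per_cycle)
  filtered <- lapply(peak$frames, function(f) {
    im <- remove_bmode(f$image, gray_tol)
    if (cool_suppression) im <- suppress_cool(im)
    im
  })
  compound <- mip_compound(filtered)
  gray <- to_grayscale(compound)
  raw_mask <- threshold_segment(gray, threshold)
  jet <- largest_island(raw_mask)
  pca <- pca_axes(jet)
  aligned <- align_to_axis(jet, pca)
  vc2d <- vc_to_image(find_vc(aligned, interior_fraction), pca)

  cone <- cone_from_meta(seq$meta)
  vc_image_mm <- lift_to_cone(vc2d$vc_px, cone)
  pf <- if (is.null(pose_frame)) peak$frames[[1]]
        else seq$frames[[pose_frame]]
  vc_tracker_mm <- to_tracker(vc_image_mm, calibration, pf$pose)

  validation <- NULL
  if (!is.null(ground_truth)) {
    fo <- flag_outlier(vc_tracker_mm, ground_truth)
    validation <- c(fo, list(retake_advised = fo$flag))
  }
  structure(list(vcw_px = vc2d$vcw_px,
                 vcw_mm = vc2d$vcw_px * seq$meta$mm_per_px,
                 vc_px = vc2d$vc_px,
                 vc_image_mm = vc_image_mm,
                 vc_tracker_mm = vc_tracker_mm,
                 frame_index = pf$index,
                 threshold = threshold,
                 pca = pca,
                 jet = jet,
                 compound = compound,
                 profile = vc2d$profile,
                 n_peak_frames = length(peak$frames),
                 validation = validation,
                 meta = seq$meta,
                 calibration = calibration),
            class = "vc_localization")
}

#' @export
print.vc_localization <- function(x, ...) {
  cat("Vena contracta localization\n")
  cat(sprintf("  VCW: %.2f px = %.2f mm\n", x$vcw_px, x$vcw_mm))
  cat(sprintf("  VC (image px):     (%.2f, %.2f)\n", x$vc_px[1], x$vc_px[2]))
  cat(sprintf("  VC (tracker mm):   (%.2f, %.2f, %.2f) via pose of frame %d\n",
              x$vc_tracker_mm[1], x$vc_tracker_mm[2], x$vc_tracker_mm[3],
              x$frame_index))
  if (!is.null(x$validation)) {
    v <- x$validation
    cat(sprintf("  Validation: %.3f mm to VC model%s\n", v$dist_vc_mm,
                if (v$flag) " [OUTLIER - retake advised]" else ""))
  }
  invisible(x)
}

#' @describeIn locate_vc detailed summary including segmentation provenance
#'   and validation distances.
#' @param object,x a `vc_localization`.
#' @param ... unused.
#' @export
summary.vc_localization <- function(object, ...) {
  x <- object
  print(x)
  cat(sprintf("  Segmentation: threshold %g, island %d px, %d peak frames compounded\n",
              x$threshold, x$jet$component_area_px, x$n_peak_frames))
  cat(sprintf("  Jet axes: major (%.3f, %.3f), moments %.1f / %.1f px^2\n",
              x$pca$major_axis[1], x$pca$major_axis[2],
              x$pca$moments[1], x$pca$moments[2]))
  cat(sprintf("  Cone lift: (%.2f, %.2f, %.2f) mm on a %g-degree half-angle cone\n",
              x$vc_image_mm[1], x$vc_image_mm[2], x$vc_image_mm[3],
              x$meta$imaging_angle_deg))
  if (!is.null(x$validation))
    cat("  ", x$validation$reason, "\n", sep = "")
  invisible(x)
}

#' @describeIn locate_vc the estimate as a named vector
#'   (vcw_mm, vc_x, vc_y, vc_z in tracker mm).
#' @export
coef.vc_localization <- function(object, ...) {
  c(vcw_mm = unname(object$vcw_mm),
    vc_x = unname(object$vc_tracker_mm[1]),
    vc_y = unname(object$vc_tracker_mm[2]),
    vc_z = unname(object$vc_tracker_mm[3]))
}

#' @describeIn locate_vc plots the compounded Doppler image with the jet
#'   island outline and the detected VC marked.
#' @export
plot.vc_localization <- function(x, ...) {
  img <- x$compound / 255
  op <- graphics::par(mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  H <- dim(img)[1]; W <- dim(img)[2]
  graphics::plot(NA, xlim = c(0.5, W + 0.5), ylim = c(H + 0.5, 0.5),
                 asp = 1, xlab = "", ylab = "",
                 main = sprintf("Compounded jet, VCW = %.2f mm", x$vcw_mm), ...)
  graphics::rasterImage(grDevices::as.raster(img), 0.5, H + 0.5, W + 0.5, 0.5)
  edge <- which(x$jet$mask, arr.ind = TRUE)
  graphics::points(edge[, 2], edge[, 1], pch = ".", col = "white")
  graphics::points(x$vc_px[2], x$vc_px[1], pch = 4, cex = 2, lwd = 2,
                   col = "cyan")
  invisible(x)
}

## ---- file-based orchestration -------------------------------------------

pipeline_keys <- c("fps", "bpm", "imaging_angle_deg", "mm_per_px", "center_px",
                   "first_peak_index", "frames_per_cycle", "threshold",
                   "gray_tol", "interior_fraction", "frames_dir", "pose_file",
                   "calibration_file", "gt_vc_file", "gt_annulus_file",
                   "output_dir", "pose_frame", "cool_suppression")

#' Validated pipeline configuration
#'
#' @param x a named list, or a path to a YAML/JSON config file. Required keys:
#'   the [acquisition_meta()] fields, `first_peak_index`, `frames_per_cycle`,
#'   `frames_dir`, `pose_file`, `calibration_file`. Optional: `threshold`
#'   (150), `gray_tol` (20), `interior_fraction` (0.1), `gt_vc_file`,
#'   `gt_annulus_file`, `output_dir`, `pose_frame`, `cool_suppression`.
#'   Unknown keys are rejected.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(x) {
  if (is.character(x)) {
    x <- if (grepl("\\.json$", x, ignore.case = TRUE))
      jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
  }
  unknown <- setdiff(names(x), pipeline_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  required <- c("fps", "bpm", "imaging_angle_deg", "mm_per_px", "center_px",
                "first_peak_index", "frames_per_cycle", "frames_dir",
                "pose_file", "calibration_file")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("missing config keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  defaults <- list(threshold = 150, gray_tol = 20, interior_fraction = 0.1,
                   cool_suppression = TRUE)
  for (k in names(defaults)) if (is.null(x[[k]])) x[[k]] <- defaults[[k]]
  # validates meta invariants early
  acquisition_meta(x$fps, x$bpm, x$imaging_angle_deg, x$mm_per_px,
                   unlist(x$center_px))
  structure(x, class = "pipeline_config")
}

#' Run the full pipeline from files on disk
#'
#' Loads the tracked sequence, calibration and optional ground truth named in
#' the config, runs [locate_vc()], and writes a results CSV
#' (`dataset, vcw_mm, vc_x, vc_y, vc_z, distance_mm, outlier_flag`) plus a
#' JSON summary into `output_dir`. A no-jet or jet-too-short condition does
#' not raise: it returns status `"retake_advised"`, signalling the
#' five-second acquisition should be retaken. With `debug_dir`, the
#' intermediate images (filtered first frame, MIP compound, grayscale, jet
#' mask) and the width profile CSV are also written.
#'
#' @param config a [pipeline_config()] (or list / config file path).
#' @param debug_dir optional directory for stage dumps.
#' @return a list of class `"vc_pipeline_result"`: `status` (`"ok"` or
#'   `"retake_advised"`), `fit` (the `vc_localization`, or NULL), `message`.
#' @export
run_pipeline <- function(config, debug_dir = NULL) {
  config <- pipeline_config(config)
  meta <- acquisition_meta(config$fps, config$bpm, config$imaging_angle_deg,
                           config$mm_per_px, unlist(config$center_px))
  seq <- load_sequence(config$frames_dir, config$pose_file, meta)
  calibration <- read_pose_file(config$calibration_file)[[1]]
  gt <- NULL
  if (!is.null(config$gt_vc_file) && !is.null(config$gt_annulus_file))
    gt <- ground_truth(read_points(config$gt_vc_file),
                       read_points(config$gt_annulus_file))
  fit <- tryCatch(
    locate_vc(seq, calibration,
              first_peak_index = config$first_peak_index,
              frames_per_cycle = config$frames_per_cycle,
              threshold = config$threshold, gray_tol = config$gray_tol,
              interior_fraction = config$interior_fraction,
              ground_truth = gt, pose_frame = config$pose_frame,
              cool_suppression = config$cool_suppression),
    vclocate_retake = function(e) e)
  if (inherits(fit, "condition")) {
    res <- structure(list(status = "retake_advised", fit = NULL,
                          message = paste0(
                            conditionMessage(fit),
                            "; it is recommended to retake the five-second imaging data")),
                     class = "vc_pipeline_result")
  } else {
    status <- if (!is.null(fit$validation) && fit$validation$flag)
      "retake_advised" else "ok"
    res <- structure(list(status = status, fit = fit,
                          message = if (status == "ok") "VC localized"
                          else "VC flagged as annulus-proximity outlier; it is recommended to retake the five-second imaging data"),
                     class = "vc_pipeline_result")
  }
  if (!is.null(config$output_dir)) write_pipeline_outputs(res, config)
  if (!is.null(debug_dir) && !is.null(res$fit))
    write_debug_outputs(res$fit, seq, config, debug_dir)
  res
}

#' @export
print.vc_pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline status: %s - %s\n", x$status, x$message))
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

write_pipeline_outputs <- function(res, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- res$fit
  row <- data.frame(
    dataset = basename(config$frames_dir),
    vcw_mm = if (is.null(fit)) NA_real_ else fit$vcw_mm,
    vc_x = if (is.null(fit)) NA_real_ else fit$vc_tracker_mm[1],
    vc_y = if (is.null(fit)) NA_real_ else fit$vc_tracker_mm[2],
    vc_z = if (is.null(fit)) NA_real_ else fit$vc_tracker_mm[3],
    distance_mm = if (is.null(fit$validation)) NA_real_
                  else fit$validation$dist_vc_mm,
    outlier_flag = if (is.null(fit$validation)) NA
                   else fit$validation$flag)
  utils::write.csv(row, file.path(config$output_dir, "vc_result.csv"),
                   row.names = FALSE)
  summary <- list(status = res$status, message = res$message)
  if (!is.null(fit)) {
    summary$vcw_mm <- fit$vcw_mm
    summary$vc_tracker_mm <- unname(fit$vc_tracker_mm)
    summary$pose_frame <- fit$frame_index
    summary$threshold <- fit$threshold
    if (!is.null(fit$validation))
      summary$validation <- list(
        distance_mm = fit$validation$dist_vc_mm,
        distance_annulus_mm = fit$validation$dist_annulus_mm,
        outlier_flag = fit$validation$flag)
  }
  jsonlite::write_json(summary, file.path(config$output_dir, "vc_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

write_debug_outputs <- function(fit, seq, config, debug_dir) {
  dir.create(debug_dir, showWarnings = FALSE, recursive = TRUE)
  first <- seq$frames[[config$first_peak_index]]$image
  filt <- suppress_cool(remove_bmode(first, config$gray_tol))
  write_frame_png(filt, file.path(debug_dir, "01_filtered_first_peak.png"))
  write_frame_png(fit$compound, file.path(debug_dir, "02_mip_compound.png"))
  gray <- to_grayscale(fit$compound)
  png::writePNG(gray / 255, file.path(debug_dir, "03_grayscale.png"))
  png::writePNG(fit$jet$mask * 1, file.path(debug_dir, "04_jet_mask.png"))
  utils::write.csv(fit$profile, file.path(debug_dir, "05_width_profile.csv"),
                   row.names = FALSE)
  invisible(fit)
}

#' Batch validation summary across datasets
#'
#' Convenience wrapper: closest-distance errors and annulus-proximity flags
#' for several localized VCs against their ground truths, summarized with
#' outliers excluded.
#'
#' @param fits list of `vc_localization` objects carrying `validation`.
#' @return a list: `per_dataset` data.frame and `stats` from [error_stats()].
#' @export
validate_batch <- function(fits) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, function(f) !is.null(f$validation), logical(1))))
  d <- vapply(fits, function(f) f$validation$dist_vc_mm, numeric(1))
  fl <- vapply(fits, function(f) f$validation$flag, logical(1))
  list(per_dataset = data.frame(dataset = seq_along(fits), distance_mm = d,
                                outlier_flag = fl),
       stats = error_stats(d, fl))
}
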