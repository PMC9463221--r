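#' Conical imaging geometry and tracker-space validation
#'
#' The forward-looking ICE probe images a conical surface; the console
#' display is an orthographic projection of that cone along the probe
#' (height) axis. The displayed (x, y) offsets from the cone apex are thus
#' the true in-plane coordinates, and the missing depth is recovered from the
#' cone geometry as `z = rho / tan(half_angle)`. The 3D image-space point is
#' then pushed through the probe calibration (image to sensor) and the
#' tracked pose (sensor to tracker).
#'
#' @name geometry3d
NULL

#' Cone model of the ICE imaging surface
#'
#' @param half_angle_deg cone half-angle from the probe axis, degrees (0, 90].
#'   90 degrees degenerates to a flat disk (z = 0 everywhere).
#' @param mm_per_px isotropic display pixel spacing (mm/pixel).
#' @param center_px (row, col) display pixel of the cone apex projection.
#' @return a list of class `"cone_model"`.
#' @export
cone_model <- function(half_angle_deg, mm_per_px, center_px) {
  if (!is.numeric(half_angle_deg) || half_angle_deg <= 0 || half_angle_deg > 90)
    stop("undefined cone geometry: half_angle_deg must lie in (0, 90]",
         call. = FALSE)
  stopifnot(mm_per_px > 0, length(center_px) == 2)
  structure(list(half_angle_deg = half_angle_deg, mm_per_px = mm_per_px,
                 center_px = as.numeric(center_px)),
            class = "cone_model")
}

#' @rdname cone_model
#' @param meta an [acquisition_meta()].
#' @export
cone_from_meta <- function(meta) {
  cone_model(meta$imaging_angle_deg, meta$mm_per_px, meta$center_px)
}

#' Lift a 2D display pixel onto the 3D conical imaging surface
#'
#' Image row maps to +y and column to +x, with the origin at the cone apex
#' projection (`center_px`); depth points away from the probe face
#' (right-handed). The planar offset `d = (vc_px - center_px) * mm_per_px`
#' has radius `rho = |d|` and the point lifts to `(d_x, d_y, rho /
#' tan(half_angle))`, so apex pixels map to the apex (0, 0, 0).
#'
#' @param vc_px (row, col) display pixel (subpixel allowed).
#' @param cone a [cone_model()].
#' @return length-3 numeric (x, y, z) in probe-image mm.
#' @export
lift_to_cone <- function(vc_px, cone) {
  stopifnot(inherits(cone, "cone_model"), length(vc_px) == 2)
  dy <- (vc_px[1] - cone$center_px[1]) * cone$mm_per_px  # row -> y
  dx <- (vc_px[2] - cone$center_px[2]) * cone$mm_per_px  # col -> x
  rho <- sqrt(dx^2 + dy^2)
  z <- rho / tan(cone$half_angle_deg * pi / 180)
  c(x = dx, y = dy, z = z)
}

#' Transform a probe-image point into tracker space
#'
#' Applies the calibration (image to sensor) then the tracked pose (sensor to
#' tracker): `p_tracker = pose %*% calibration %*% p`.
#'
#' @param p_image_mm length-3 point in probe-image mm.
#' @param calibration image-to-sensor rigid transform.
#' @param pose sensor-to-tracker rigid transform.
#' @return length-3 point in tracker mm.
#' @export
to_tracker <- function(p_image_mm, calibration, pose) {
  apply_transform(pose, apply_transform(calibration, as.numeric(p_image_mm)))
}

#' Closest distance from a point to a point-set model
#'
#' @param p_mm length-3 point (tracker mm).
#' @param model N x 3 matrix of model points (tracker mm).
#' @return the minimum Euclidean distance (mm).
#' @export
closest_distance <- function(p_mm, model) {
  model <- as.matrix(model)
  if (nrow(model) == 0) stop("empty point-set model", call. = FALSE)
  stopifnot(ncol(model) == 3, length(p_mm) == 3)
  d2 <- (model[, 1] - p_mm[1])^2 + (model[, 2] - p_mm[2])^2 +
    (model[, 3] - p_mm[3])^2
  sqrt(min(d2))
}

#' Ground-truth vena contracta and annulus models
#'
#' Point sets traced in tracker space with a tracked needle: one around the
#' periphery of the regurgitant orifice (the VC model), one along the valve
#' annulus (a landmark used to flag mislocalized detections).
#'
#' @param vc_points_mm N x 3 matrix (N >= 3), tracker mm.
#' @param annulus_points_mm M x 3 matrix (M >= 3), tracker mm.
#' @return a list of class `"ground_truth"`.
#' @export
ground_truth <- function(vc_points_mm, annulus_points_mm) {
  vc_points_mm <- as.matrix(vc_points_mm)
  annulus_points_mm <- as.matrix(annulus_points_mm)
  stopifnot(ncol(vc_points_mm) == 3, nrow(vc_points_mm) >= 3,
            ncol(annulus_points_mm) == 3, nrow(annulus_points_mm) >= 3)
  structure(list(vc_points_mm = vc_points_mm,
                 annulus_points_mm = annulus_points_mm),
            class = "ground_truth")
}

#' Read or write a point-set model
#'
#' Plain text, one `x y z` triple (mm) per line.
#'
#' @param path file path.
#' @return `read_points()` returns an N x 3 numeric matrix.
#' @export
read_points <- function(path) {
  m <- as.matrix(utils::read.table(path, col.names = c("x", "y", "z")))
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' @rdname read_points
#' @param points N x 3 matrix.
#' @export
write_points <- function(points, path) {
  utils::write.table(points, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Flag a detected VC that sits closer to the annulus than to the VC model
#'
#' A detection "positioned too close to the annulus" is the pipeline's known
#' failure mode (insufficient Doppler capture); it is flagged by the
#' scale-free comparative rule: outlier when the distance to the annulus
#' model is strictly smaller than the distance to the VC model. A flagged
#' run should be re-acquired.
#'
#' @param vc_mm detected VC, length-3 tracker mm.
#' @param gt a [ground_truth()].
#' @return a list: `flag` (logical), `dist_vc_mm`, `dist_annulus_mm`,
#'   `reason` (character).
#' @export
flag_outlier <- function(vc_mm, gt) {
  stopifnot(inherits(gt, "ground_truth"))
  d_vc <- closest_distance(vc_mm, gt$vc_points_mm)
  d_an <- closest_distance(vc_mm, gt$annulus_points_mm)
  flag <- d_an < d_vc
  list(flag = flag, dist_vc_mm = d_vc, dist_annulus_mm = d_an,
       reason = sprintf(
         "distance to VC model %.3f mm, to annulus %.3f mm: %s",
         d_vc, d_an,
         if (flag) "closer to annulus - outlier, retake advised"
         else "closer to VC model - accepted"))
}

#' Summary statistics of validation distances, excluding flagged outliers
#'
#' @param distances numeric vector of closest-distance errors (mm).
#' @param flags logical vector of outlier flags, same length.
#' @return a list: `mean_mm`, `sd_mm` (sample SD, divisor n - 1; 0 for a
#'   single value), `n`, `n_outliers`.
#' @export
error_stats <- function(distances, flags = rep(FALSE, length(distances))) {
  stopifnot(length(distances) == length(flags))
  keep <- !flags
  if (!any(keep))
    stop("no valid data: every entry is flagged as an outlier", call. = FALSE)
  d <- distances[keep]
  list(mean_mm = mean(d),
       sd_mm = if (length(d) > 1) stats::sd(d) else 0,
       n = length(d),
       n_outliers = sum(flags))
}
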