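#' Synthetic pulsatile Doppler-jet sequences with known ground truth
#'
#' Renders tracked color-Doppler-like frame sequences in which everything the
#' pipeline estimates is known by construction: a warm (red-to-yellow)
#' hourglass jet with an exact neck width and position, cool (blue-dominant)
#' inflow blobs, grayscale speckle background, cardiac-phase pulsation, and
#' per-frame probe poses with bounded jitter. The renderer emulates only the
#' features the algorithm consumes - shape, color ordering and pulsatility -
#' not acoustic physics.
#'
#' @name synthetic_data
NULL

#' Parameters of the synthetic Doppler jet scene
#'
#' The jet is two opposed triangles (a converging and a diverging cone)
#' joined at the neck - the classic hourglass of a regurgitant jet - drawn
#' along `jet_angle_deg` with its narrowest extent equal to `neck_width_px`
#' exactly at `neck_px` (for even widths the axis is offset half a pixel so
#' the rasterized extent is exact; `neck_center_px()` returns the effective
#' subpixel neck). Warm pixels ramp from red at the jet edge to yellow at the
#' core, with peak-frame luminance above 150; cool inflow and speckle stay
#' below 130 after warm filtering. Jet brightness and length are modulated by
#' cardiac phase: full at `cycle_peak_frame` within each cycle, dim in the
#' two following frames, absent in diastole.
#'
#' @param size (H, W) image dimensions in pixels.
#' @param neck_px (row, col) true vena contracta pixel.
#' @param neck_width_px neck extent in pixels (>= 2).
#' @param jet_length_px full jet length along its axis at peak.
#' @param jet_max_width_px jet extent at its wide ends (default
#'   `max(3 * neck_width_px, neck_width_px + 12)`).
#' @param jet_angle_deg jet-axis orientation, degrees from the +column axis.
#' @param inflow_regions list of cool blobs, each `list(center = c(row, col),
#'   radii = c(r_row, r_col))`.
#' @param speckle_level grayscale background amplitude (0-255).
#' @param cycle_peak_frame 1-based frame-within-cycle of maximal jet.
#' @param frames_per_cycle_period cardiac cycle length in frames (fps * 60 /
#'   bpm of the acquisition it emulates).
#' @param seed RNG seed; a fixed seed gives bit-identical renders.
#' @return a list of class `"jet_scene_params"`.
#' @export
jet_scene_params <- function(size = c(200, 200),
                             neck_px = c(100, 100),
                             neck_width_px = 5,
                             jet_length_px = 60,
                             jet_max_width_px = NULL,
                             jet_angle_deg = 30,
                             inflow_regions = list(list(center = c(60, 40),
                                                        radii = c(14, 10))),
                             speckle_level = 80,
                             cycle_peak_frame = 3,
                             frames_per_cycle_period = 15,
                             seed = 1) {
  stopifnot(neck_width_px >= 2,
            neck_px[1] >= 1, neck_px[1] <= size[1],
            neck_px[2] >= 1, neck_px[2] <= size[2],
            jet_length_px > 0, speckle_level >= 0, speckle_level <= 255,
            cycle_peak_frame >= 1,
            cycle_peak_frame <= frames_per_cycle_period)
  if (is.null(jet_max_width_px))
    jet_max_width_px <- max(3 * neck_width_px, neck_width_px + 12)
  stopifnot(jet_max_width_px > neck_width_px)
  structure(list(size = as.integer(size), neck_px = as.numeric(neck_px),
                 neck_width_px = neck_width_px,
                 jet_length_px = jet_length_px,
                 jet_max_width_px = jet_max_width_px,
                 jet_angle_deg = jet_angle_deg,
                 inflow_regions = inflow_regions,
                 speckle_level = speckle_level,
                 cycle_peak_frame = as.integer(cycle_peak_frame),
                 frames_per_cycle_period = frames_per_cycle_period,
                 seed = as.integer(seed)),
            class = "jet_scene_params")
}

# unit jet-frame axes in (row, col): e1 along the jet, e2 across it
jet_axes <- function(params) {
  th <- params$jet_angle_deg * pi / 180
  list(e1 = c(sin(th), cos(th)), e2 = c(cos(th), -sin(th)))
}

# half-pixel minor offset making even neck extents rasterize exactly
jet_voffset <- function(params) if (params$neck_width_px %% 2 == 0) 0.5 else 0

#' Effective subpixel neck center of a synthetic scene
#'
#' @param params a [jet_scene_params()].
#' @return (row, col), equal to `neck_px` for odd neck widths and offset half
#'   a pixel across the jet for even widths.
#' @export
neck_center_px <- function(params) {
  ax <- jet_axes(params)
  params$neck_px + jet_voffset(params) * ax$e2
}

# cardiac-phase amplitude of a frame: 1 at the peak frame of each cycle,
# 0.5 for the two frames after it, 0 in diastole
cycle_amplitude <- function(params, frame_index) {
  P <- params$frames_per_cycle_period
  rel <- (round((frame_index - 1) %% P) - (params$cycle_peak_frame - 1)) %% round(P)
  if (rel == 0) 1 else if (rel <= 2) 0.5 else 0
}

#' Render one synthetic Doppler frame
#'
#' @param params a [jet_scene_params()].
#' @param frame_index 1-based frame ordinal; fixes both the cardiac phase and
#'   the per-frame speckle realization.
#' @return H x W x 3 8-bit RGB integer array.
#' @export
render_frame <- function(params, frame_index) {
  H <- params$size[1]; W <- params$size[2]
  s <- as.integer((as.numeric(params$seed) %% 100000 * 20011 + frame_index) %%
                    2147483647)
  img <- with_seed(s, {
    g <- matrix(sample.int(params$speckle_level + 1, H * W, replace = TRUE) - 1L,
                H, W)
    jit <- matrix(sample.int(11, H * W, replace = TRUE) - 6L, H, W)
    a <- array(0L, c(H, W, 3))
    for (ch in 1:3) a[, , ch] <- pmax(0L, pmin(255L, g + (ch == 2L) * jit))
    a
  })
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (blob in params$inflow_regions) {
    inside <- ((rr - blob$center[1]) / blob$radii[1])^2 +
      ((cc - blob$center[2]) / blob$radii[2])^2 <= 1
    img[, , 1][inside] <- 40L
    img[, , 2][inside] <- 60L
    img[, , 3][inside] <- 200L
  }
  amp <- cycle_amplitude(params, frame_index)
  if (amp > 0) {
    ax <- jet_axes(params)
    voff <- jet_voffset(params)
    dr <- rr - params$neck_px[1]
    dc <- cc - params$neck_px[2]
    u <- dr * ax$e1[1] + dc * ax$e1[2]
    v <- dr * ax$e2[1] + dc * ax$e2[2] - voff
    half_len <- params$jet_length_px / 2 * amp
    hw_neck <- (params$neck_width_px - 1) / 2
    hw_max <- (params$jet_max_width_px - 1) / 2
    hw <- hw_neck + (hw_max - hw_neck) * abs(u) / half_len
    on <- abs(u) <= half_len & abs(v) <= hw
    core <- pmax(0, 1 - abs(v) / pmax(hw, 1e-9))  # 1 at the jet axis
    img[, , 1][on] <- as.integer(round(amp * 255))
    img[, , 2][on] <- as.integer(round(amp * (160 + 90 * core[on])))
    img[, , 3][on] <- 0L
  }
  img
}

#' Generate a complete tracked synthetic dataset with ground truth
#'
#' Produces a [frame_sequence()] of `n_seconds` of imaging (one pose per
#' frame: identity plus bounded rigid jitter, emulating a hand-held but
#' steady probe), together with ground-truth point models consistent with the
#' rendered scene under the declared cone model and transform chain: a VC
#' ring of radius `neck_width / 2` (mm) centered on the true tracker-space
#' vena contracta, and a larger annulus ring offset in the valve plane. The
#' valve plane is taken perpendicular to the jet axis mapped into tracker
#' space.
#'
#' @param params a [jet_scene_params()]; its cycle period is overridden by
#'   `fps * 60 / bpm` from `meta` so scene and gating agree.
#' @param meta an [acquisition_meta()].
#' @param n_seconds acquisition length in seconds (>= one cardiac cycle).
#' @param pose_jitter list with `trans_mm` and `rot_deg` bounds on the
#'   per-frame rigid perturbation.
#' @param calibration image-to-sensor rigid transform (default: a fixed
#'   rotation plus offset, so the chain is exercised end to end).
#' @param annulus_radius_mm radius of the synthetic annulus ring.
#' @param annulus_offset_mm in-plane offset of the annulus center from the VC.
#' @return a list: `sequence`, `ground_truth`, `vc_true_mm` (tracker),
#'   `vc_true_px` (subpixel image neck), `calibration`, `first_peak_index`,
#'   `params`.
#' @export
generate_dataset <- function(params, meta, n_seconds = 5,
                             pose_jitter = list(trans_mm = 0.5, rot_deg = 0.5),
                             calibration = NULL,
                             annulus_radius_mm = 15,
                             annulus_offset_mm = 2) {
  stopifnot(inherits(params, "jet_scene_params"),
            inherits(meta, "acquisition_meta"),
            n_seconds >= 60 / meta$bpm)
  params$frames_per_cycle_period <- cycle_period(meta)
  if (is.null(calibration))
    calibration <- rigid_from_axis_angle(c(0, 1, 0), 20, c(12, -4, 30))
  n_frames <- round(n_seconds * meta$fps)
  s <- as.integer((as.numeric(params$seed) %% 100000 * 20011 + 777) %% 2147483647)
  poses <- with_seed(s, lapply(seq_len(n_frames), function(i) {
    ax <- stats::rnorm(3)
    rigid_from_axis_angle(ax, stats::runif(1, 0, pose_jitter$rot_deg),
                          stats::runif(3, -pose_jitter$trans_mm,
                                       pose_jitter$trans_mm))
  }))
  frames <- lapply(seq_len(n_frames), function(i)
    tracked_frame(render_frame(params, i), i, poses[[i]]))
  seq <- frame_sequence(frames, meta)

  first_peak <- params$cycle_peak_frame
  cone <- cone_from_meta(meta)
  vc_px <- neck_center_px(params)
  vc_true <- to_tracker(lift_to_cone(vc_px, cone), calibration,
                        poses[[first_peak]])

  # jet axis direction in tracker space -> valve plane basis (t1, t2)
  ax <- jet_axes(params)
  q_px <- vc_px + 5 * ax$e1
  q_true <- to_tracker(lift_to_cone(q_px, cone), calibration,
                       poses[[first_peak]])
  n <- q_true - vc_true; n <- n / sqrt(sum(n^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- c(n[2] * ref[3] - n[3] * ref[2],
          n[3] * ref[1] - n[1] * ref[3],
          n[1] * ref[2] - n[2] * ref[1])
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(n[2] * t1[3] - n[3] * t1[2],
          n[3] * t1[1] - n[1] * t1[3],
          n[1] * t1[2] - n[2] * t1[1])

  ring <- function(center, radius, k = 36) {
    t(vapply(seq(0, 2 * pi, length.out = k + 1)[-(k + 1)], function(a)
      center + radius * (cos(a) * t1 + sin(a) * t2), numeric(3)))
  }
  r_vc <- params$neck_width_px * meta$mm_per_px / 2
  gt <- ground_truth(ring(vc_true, r_vc),
                     ring(vc_true + annulus_offset_mm * t1, annulus_radius_mm))

  list(sequence = seq, ground_truth = gt,
       vc_true_mm = vc_true, vc_true_px = vc_px,
       calibration = calibration, first_peak_index = first_peak,
       params = params)
}

#' Delete frames from a sequence, emulating frame-grabber misses
#'
#' Removes the given frames and reindexes the remainder consecutively, the
#' way a dropped capture shifts all later frames earlier. Deleting the peak
#' frames of several cycles breaks the cardiac gating alignment and
#' reproduces the pipeline's no-jet / annulus-proximity failure modes.
#'
#' @param seq a [frame_sequence()].
#' @param indices 1-based positions to delete.
#' @return a [frame_sequence()] with the surviving frames reindexed 1..n.
#' @export
drop_frames <- function(seq, indices) {
  stopifnot(inherits(seq, "frame_sequence"))
  keep <- setdiff(seq_along(seq$frames), indices)
  if (length(keep) == 0) stop("cannot drop every frame", call. = FALSE)
  frames <- lapply(seq_along(keep), function(i) {
    f <- seq$frames[[keep[i]]]
    f$index <- i
    f
  })
  frame_sequence(frames, seq$meta)
}
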