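#' Acquisition metadata for a tracked Doppler sequence
#'
#' Bundles the console and tracker settings the pipeline needs: the frame
#' rate of the frame grabber, the phantom/patient heart rate used for cardiac
#' gating, the imaging (cone half-) angle of the forward-looking ICE probe,
#' the in-plane pixel spacing, and the display pixel of the probe axis.
#'
#' @param fps frames per second of the recorded stream (Hz).
#' @param bpm heart rate in beats per minute; together with `fps` it fixes the
#'   cardiac cycle period in frames.
#' @param imaging_angle_deg cone half-angle measured from the probe axis, in
#'   degrees (0, 90]. If the console reports the full opening angle, pass half
#'   of it.
#' @param mm_per_px isotropic in-plane pixel spacing (mm/pixel).
#' @param center_px (row, col) display pixel of the probe axis (cone apex
#'   projection).
#' @return a list of class `"acquisition_meta"`.
#' @examples
#' acquisition_meta(fps = 15, bpm = 60, imaging_angle_deg = 30,
#'                  mm_per_px = 0.2, center_px = c(100, 100))
#' @export
acquisition_meta <- function(fps, bpm, imaging_angle_deg, mm_per_px, center_px) {
  stopifnot(is.numeric(fps), length(fps) == 1, fps > 0,
            is.numeric(bpm), length(bpm) == 1, bpm > 0,
            is.numeric(mm_per_px), length(mm_per_px) == 1, mm_per_px > 0,
            is.numeric(center_px), length(center_px) == 2)
  if (!is.numeric(imaging_angle_deg) || imaging_angle_deg <= 0 ||
      imaging_angle_deg > 90)
    stop("imaging_angle_deg must lie in (0, 90]", call. = FALSE)
  structure(list(fps = fps, bpm = bpm,
                 imaging_angle_deg = imaging_angle_deg,
                 mm_per_px = mm_per_px,
                 center_px = as.numeric(center_px)),
            class = "acquisition_meta")
}

#' Cardiac cycle period in frames
#'
#' @param meta an [acquisition_meta()].
#' @return `fps * 60 / bpm` (not rounded; callers round per cycle).
#' @export
cycle_period <- function(meta) meta$fps * 60 / meta$bpm

#' A single tracked ultrasound frame
#'
#' @param image H x W x 3 integer array, 8-bit RGB channels (0-255).
#' @param index frame ordinal within its sequence (1-based).
#' @param pose sensor-to-tracker rigid transform reported by the EM tracker.
#' @return a list of class `"tracked_frame"`.
#' @export
tracked_frame <- function(image, index, pose) {
  stopifnot(is.array(image), length(dim(image)) == 3, dim(image)[3] == 3)
  if (min(image) < 0 || max(image) > 255)
    stop("image channels must be 8-bit (0-255)", call. = FALSE)
  structure(list(image = image, index = as.integer(index),
                 pose = rigid_transform(pose)),
            class = "tracked_frame")
}

#' An ordered tracked frame sequence
#'
#' @param frames list of [tracked_frame()]s with constant dimensions and
#'   strictly increasing indices.
#' @param meta an [acquisition_meta()].
#' @return a list of class `"frame_sequence"`.
#' @export
frame_sequence <- function(frames, meta) {
  stopifnot(length(frames) >= 1, inherits(meta, "acquisition_meta"))
  dims <- vapply(frames, function(f) dim(f$image)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames in a sequence must share image dimensions", call. = FALSE)
  idx <- vapply(frames, `[[`, integer(1), "index")
  if (any(diff(idx) <= 0))
    stop("frame indices must be strictly increasing", call. = FALSE)
  structure(list(frames = frames, meta = meta), class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]]$image)
  cat(sprintf("Tracked Doppler frame sequence: %d frames of %d x %d px\n",
              length(x$frames), d[1], d[2]))
  cat(sprintf("  %g fps, %g bpm (cycle period %.2f frames), %g mm/px\n",
              x$meta$fps, x$meta$bpm, cycle_period(x$meta), x$meta$mm_per_px))
  invisible(x)
}

## ---- pose and metadata files -------------------------------------------

#' Read or write probe poses
#'
#' Poses are stored as plain text: one 4x4 row-major matrix per line, 16
#' whitespace-separated numbers, in frame order.
#'
#' @param path file path.
#' @return `read_pose_file()` returns a list of `rigid_transform`s.
#' @export
read_pose_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    v <- as.numeric(strsplit(trimws(lines[[i]]), "\\s+")[[1]])
    if (length(v) != 16)
      stop(sprintf("pose line %d: expected 16 numbers, found %d", i, length(v)),
           call. = FALSE)
    tryCatch(rigid_transform(matrix(v, 4, 4, byrow = TRUE)),
             error = function(e) stop(sprintf("pose %d: %s", i, conditionMessage(e)),
                                      call. = FALSE))
  })
}

#' @rdname read_pose_file
#' @param poses list of 4x4 rigid transforms.
#' @export
write_pose_file <- function(poses, path) {
  lines <- vapply(poses, function(m) paste(format(t(m), digits = 17),
                                           collapse = " "), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write acquisition metadata as YAML (or JSON)
#'
#' @param path a `.yaml`/`.yml` or `.json` file with keys `fps`, `bpm`,
#'   `imaging_angle_deg`, `mm_per_px`, `center_px`.
#' @return an [acquisition_meta()].
#' @export
read_meta <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  acquisition_meta(fps = x$fps, bpm = x$bpm,
                   imaging_angle_deg = x$imaging_angle_deg,
                   mm_per_px = x$mm_per_px, center_px = unlist(x$center_px))
}

#' @rdname read_meta
#' @param meta an [acquisition_meta()].
#' @export
write_meta <- function(meta, path) {
  yaml::write_yaml(unclass(meta), path)
  invisible(path)
}

## ---- sequence I/O -------------------------------------------------------

# png::readPNG returns doubles in [0,1]; frames are kept as 8-bit integers
read_frame_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]
  array(as.integer(round(a * 255)), dim(a))
}

write_frame_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Load a tracked frame sequence from disk
#'
#' Pairs the lexicographically ordered image files in `frame_dir` with the
#' poses in `pose_file` by order.
#'
#' @param frame_dir directory of 8-bit PNG frames, ordered by filename.
#' @param pose_file plain-text pose file (see [read_pose_file()]).
#' @param meta an [acquisition_meta()], or a path readable by [read_meta()].
#' @return a [frame_sequence()].
#' @export
load_sequence <- function(frame_dir, pose_file, meta) {
  if (is.character(meta)) meta <- read_meta(meta)
  files <- sort(list.files(frame_dir, pattern = "\\.png$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0)
    stop("no PNG frames found in ", frame_dir, call. = FALSE)
  poses <- read_pose_file(pose_file)
  if (length(files) != length(poses))
    stop(sprintf("pairing error: %d frames but %d poses",
                 length(files), length(poses)), call. = FALSE)
  frames <- lapply(seq_along(files), function(i)
    tracked_frame(read_frame_png(files[[i]]), i, poses[[i]]))
  frame_sequence(frames, meta)
}

#' Save a tracked frame sequence to disk
#'
#' Writes zero-padded PNG frames, the pose file, and a metadata YAML so that
#' [load_sequence()] round-trips images bit-exactly.
#'
#' @param seq a [frame_sequence()].
#' @param frame_dir output directory (created if needed).
#' @param pose_file output pose file path.
#' @param meta_file optional output metadata YAML path.
#' @return `frame_dir`, invisibly.
#' @export
save_sequence <- function(seq, frame_dir, pose_file, meta_file = NULL) {
  dir.create(frame_dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(seq$frames)
  for (i in seq_len(n))
    write_frame_png(seq$frames[[i]]$image,
                    file.path(frame_dir, sprintf("frame_%04d.png", i)))
  write_pose_file(lapply(seq$frames, `[[`, "pose"), pose_file)
  if (!is.null(meta_file)) write_meta(seq$meta, meta_file)
  invisible(frame_dir)
}

## ---- cardiac gating -----------------------------------------------------

#' Select the peak-regurgitation frames of every cardiac cycle
#'
#' The user identifies the first frame showing maximal regurgitation and how
#' many consecutive frames to keep per cycle; this function extracts that
#' window from every complete cardiac cycle, using the cycle period implied
#' by `fps` and `bpm` (15 frames at 15 fps / 60 bpm). Non-integer periods are
#' handled by rounding each cycle's start index, so gating does not drift.
#' Incomplete trailing cycles are dropped.
#'
#' @param seq a [frame_sequence()].
#' @param first_peak_index 1-based index of the first peak frame.
#' @param frames_per_cycle number of consecutive frames to keep per cycle.
#' @return a [frame_sequence()] of the selected frames (original indices
#'   preserved in each frame's `index`).
#' @export
select_peak_frames <- function(seq, first_peak_index, frames_per_cycle) {
  stopifnot(inherits(seq, "frame_sequence"))
  n <- length(seq$frames)
  if (first_peak_index < 1 || first_peak_index > n)
    stop("first_peak_index out of range", call. = FALSE)
  P <- cycle_period(seq$meta)
  if (frames_per_cycle < 1 || frames_per_cycle > P)
    stop("frames_per_cycle must be between 1 and the cycle period", call. = FALSE)
  idx <- integer(0)
  k <- 0
  repeat {
    start <- round(first_peak_index - 1 + k * P) + 1
    window <- start:(start + frames_per_cycle - 1)
    if (max(window) > n) break  # incomplete cycle: dropped
    idx <- c(idx, window)
    k <- k + 1
  }
  if (length(idx) == 0)
    stop("no complete cardiac cycle fits the sequence", call. = FALSE)
  frame_sequence(seq$frames[idx], seq$meta)
}
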