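#' Intensity video stack
#'
#' Container for a grayscale time-lapse stack: a `T x H x W` array of
#' non-negative intensities with its frame interval (s) and optional pixel
#' size (nm). Frame `time_zero_frame` maps to t = 0; earlier frames are
#' conventionally dropped on load.
#'
#' @param data Numeric `T x H x W` array (time first).
#' @param frame_interval Frame interval in seconds.
#' @param pixel_size Pixel size in nm (default 24.75, the oversampled PVM
#'   pixel pitch).
#' @param time_zero_frame 1-based index of the frame taken as t = 0.
#' @return Object of class `intensity_video`.
#' @export
intensity_video <- function(data, frame_interval, pixel_size = 24.75,
                            time_zero_frame = 1L) {
  if (length(dim(data)) != 3L) stop("`data` must be a T x H x W array", call. = FALSE)
  if (dim(data)[1] < 2L) stop("a video needs at least 2 frames", call. = FALSE)
  if (!all(is.finite(data))) stop("intensities must be finite", call. = FALSE)
  stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  structure(
    list(data = data, frame_interval = frame_interval, pixel_size = pixel_size,
         time_zero_frame = as.integer(time_zero_frame)),
    class = "intensity_video"
  )
}

#' @export
print.intensity_video <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<intensity_video> %d frames of %d x %d px, dt = %.4f s (%.1f s total)\n",
              d[1], d[2], d[3], x$frame_interval, (d[1] - 1) * x$frame_interval))
  invisible(x)
}

#' Frame times of a video
#'
#' @param video An [intensity_video()].
#' @return Numeric vector of frame times in seconds (frame
#'   `time_zero_frame` is 0).
#' @export
video_times <- function(video) {
  (seq_len(dim(video$data)[1]) - video$time_zero_frame) * video$frame_interval
}

#' Per-pixel trace matrix of a video
#'
#' Flattens the stack into a `T x N` matrix with one column per pixel in
#' column-major ROI order (the pixel indexing used throughout).
#'
#' @param video An [intensity_video()].
#' @return `T x (H*W)` numeric matrix.
#' @export
pixel_traces <- function(video) {
  d <- dim(video$data)
  matrix(video$data, d[1], d[2] * d[3])
}

#' Load a video stack from disk
#'
#' Reads either a multi-page grayscale TIFF or a directory of ordered
#' single-frame images (TIFF or PNG, sorted by file name). RGB frames are
#' converted to luma via [to_grayscale()]. Frames before `start_frame` are
#' dropped, so that frame `start_frame` maps to t = 0 (the digitization
#' convention for the PVM experiment, where frame 200 is time zero).
#'
#' TIFF pixel values are returned on the `[0, 1]` scale used by the tiff
#' package and multiplied by `scale` (use the factor reported by
#' [write_video_frames()] to recover original intensity units).
#'
#' @param path Multi-page TIFF file or directory of frame images.
#' @param frame_interval Frame interval in seconds.
#' @param pixel_size Pixel size in nm.
#' @param start_frame 1-based index of the first frame to keep.
#' @param scale Multiplier applied to the `[0, 1]` pixel values.
#' @return An [intensity_video()].
#' @export
load_video_frames <- function(path, frame_interval, pixel_size = 24.75,
                              start_frame = 1L, scale = 1) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("no frame images found in ", path, call. = FALSE)
    frames <- lapply(files, read_frame)
  } else if (file.exists(path)) {
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
  } else {
    stop("cannot read video input: ", path, call. = FALSE)
  }
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) to_grayscale(f) else f
  })
  if (scale != 1) frames <- lapply(frames, function(f) f * scale)
  shp <- vapply(frames, function(f) paste(dim(f), collapse = "x"), "")
  if (length(unique(shp)) != 1L) {
    stop("inconsistent frame shapes across the stack", call. = FALSE)
  }
  start_frame <- as.integer(start_frame)
  if (start_frame < 1L || start_frame > length(frames) - 1L) {
    stop("`start_frame` outside the stack", call. = FALSE)
  }
  frames <- frames[start_frame:length(frames)]
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  data <- array(0, c(length(frames), h, w))
  for (j in seq_along(frames)) data[j, , ] <- frames[[j]]
  intensity_video(data, frame_interval = frame_interval, pixel_size = pixel_size)
}

read_frame <- function(file) {
  if (grepl("\\.png$", file, ignore.case = TRUE)) {
    stop("PNG frame input requires the png package frame-by-frame; ",
         "use TIFF frames", call. = FALSE)
  }
  tiff::readTIFF(file)
}

#' Write a video stack as a multi-page TIFF
#'
#' Intensities are normalized by `scale` (default: their maximum) into the
#' `[0, 1]` range expected by the TIFF writer and stored as 32-bit
#' samples; a write-then-load round trip with the returned scale recovers
#' the stack to within the 2^-32 quantization of the format.
#'
#' @param video An [intensity_video()].
#' @param path Output file path.
#' @param scale Normalization factor; pass it to
#'   [load_video_frames()]'s `scale` to restore original units.
#' @return The scale factor used, invisibly.
#' @export
write_video_frames <- function(video, path, scale = max(video$data)) {
  d <- dim(video$data)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(d[1]), function(j) {
    m <- video$data[j, , ] / scale
    dim(m) <- d[2:3]
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(scale)
}

#' Convert RGB frames to grayscale luma
#'
#' Applies ITU-R BT.601 luma weights (0.299 R + 0.587 G + 0.114 B) along
#' the last axis. Grayscale input (no trailing channel axis) is passed
#' through unchanged.
#'
#' @param x Array whose last dimension has length 3 (H x W x 3 or
#'   T x H x W x 3), or a grayscale array.
#' @return Array with the channel axis collapsed.
#' @export
to_grayscale <- function(x) {
  d <- dim(x)
  if (is.null(d) || d[length(d)] != 3L) {
    # 2D matrices and time stacks whose trailing axis is not a channel
    # count pass through; an explicit 4-channel (RGBA) axis is rejected
    if (!is.null(d) && length(d) == 2L) return(x)
    if (!is.null(d) && length(d) == 3L && d[3L] != 4L) return(x)
    stop("last axis must hold 3 RGB channels", call. = FALSE)
  }
  w <- c(0.299, 0.587, 0.114)
  nlead <- prod(d[-length(d)])
  m <- matrix(x, nlead, 3L)
  y <- drop(m %*% w)
  if (length(d) > 2L) dim(y) <- d[-length(d)]
  y
}

#' Region-of-interest specification
#'
#' A square ROI given by its top-left corner (1-based row/col of the frame)
#' and side length in pixels.
#'
#' @param top,left 1-based corner indices.
#' @param side Side length (px).
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(top = 1L, left = 1L, side) {
  top <- as.integer(top); left <- as.integer(left); side <- as.integer(side)
  if (side < 1L || top < 1L || left < 1L) stop("invalid ROI", call. = FALSE)
  structure(list(top = top, left = left, side = side), class = "roi_spec")
}

#' Extract a square region of interest
#'
#' @param video An [intensity_video()].
#' @param roi An [roi_spec()]; must lie fully inside the frame. A 180-px
#'   ROI yields 32,400 pixel traces.
#' @return An [intensity_video()] of size `T x side x side`.
#' @export
extract_roi <- function(video, roi) {
  d <- dim(video$data)
  if (roi$top + roi$side - 1L > d[2] || roi$left + roi$side - 1L > d[3]) {
    stop("ROI exceeds the frame", call. = FALSE)
  }
  rows <- roi$top:(roi$top + roi$side - 1L)
  cols <- roi$left:(roi$left + roi$side - 1L)
  out <- video
  out$data <- video$data[, rows, cols, drop = FALSE]
  out
}

#' Smooth a trace with a centered sliding-window average
#'
#' The window length in seconds is converted to an odd number of steps
#' (`round(window_seconds / frame_interval)`, forced odd so the window is
#' centered); edges use shrinking windows rather than reflection so
#' early-time transitions are not biased in position. A 15.2-s window at
#' dt = 0.38974 s is 39 steps.
#'
#' @param trace Numeric vector of intensities.
#' @param window_seconds Window length (s).
#' @param frame_interval Frame interval (s).
#' @return Smoothed trace, same length.
#' @export
smooth_trace <- function(trace, window_seconds, frame_interval) {
  stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  if (window_seconds < frame_interval) {
    stop("window must be at least one frame interval", call. = FALSE)
  }
  roll_mean(trace, odd_window(window_seconds / frame_interval))
}

#' Optics calibration
#'
#' @param wavelength Illumination wavelength lambda (nm).
#' @param numerical_aperture Objective NA (0 < NA <= 1.7).
#' @param pixel_size Camera pixel size at the sample (nm).
#' @return Object of class `optics_calibration`.
#' @export
optics_calibration <- function(wavelength = 500, numerical_aperture = 1.45,
                               pixel_size = 24.75) {
  stopifnot_scalar(wavelength, "wavelength", positive = TRUE)
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  if (!is.numeric(numerical_aperture) || numerical_aperture <= 0 ||
      numerical_aperture > 1.7) {
    stop("numerical aperture must lie in (0, 1.7]", call. = FALSE)
  }
  structure(list(wavelength = wavelength,
                 numerical_aperture = numerical_aperture,
                 pixel_size = pixel_size),
            class = "optics_calibration")
}

#' Theoretical diffraction limit
#'
#' \eqn{\Delta x = \lambda / (2 NA)}; for lambda = 500 nm and NA = 1.45
#' this is 172 nm.
#'
#' @param cal An [optics_calibration()].
#' @return Resolution limit in nm.
#' @export
diffraction_limit <- function(cal = optics_calibration()) {
  cal$wavelength / (2 * cal$numerical_aperture)
}
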