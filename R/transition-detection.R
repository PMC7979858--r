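#' Negated intensity derivative of a trace
#'
#' Computes \eqn{-\partial I/\partial t} by central finite differences
#' (one-sided at the ends), so that peaks mark the maximum rate of
#' intensity decrease, then applies a centered moving-average smoothing
#' (default 7.78 s). The input trace is expected to be pre-smoothed with
#' [smooth_trace()] (15.2 s by default in the pipeline).
#'
#' @param trace Numeric intensity trace.
#' @param frame_interval Frame interval (s).
#' @param smooth_seconds Moving-average window for the derivative (s);
#'   `0` disables the extra smoothing.
#' @return Numeric vector of \eqn{-dI/dt} (intensity units per second),
#'   same length as `trace`.
#' @export
negated_derivative <- function(trace, frame_interval, smooth_seconds = 7.78) {
  if (length(trace) < 3L) stop("trace must have at least 3 points", call. = FALSE)
  stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  d <- -central_diff(trace) / frame_interval
  if (smooth_seconds > 0) d <- roll_mean(d, odd_window(smooth_seconds / frame_interval))
  d
}

central_diff <- function(x) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  d[1L] <- x[2L] - x[1L]
  d[n] <- x[n] - x[n - 1L]
  d
}

central_diff_mat <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, ncol(m))
  d[2:(n - 1L), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2L), , drop = FALSE]) / 2
  d[1L, ] <- m[2L, ] - m[1L, ]
  d[n, ] <- m[n, ] - m[n - 1L, ]
  d
}

#' Peak-finding parameters
#'
#' Parameters of the derivative peak finder, following the classic
#' slope/amplitude-threshold findpeaks design: the derivative trace is
#' smoothed (`smooth_width` points of `smooth_type`), candidate peaks are
#' downward zero crossings of the point-to-point slope of that smoothed
#' signal, gated by `slope_threshold` and `amp_threshold`, and each
#' candidate is fit by a Gaussian (parabola on log heights) over
#' `fit_width` points grouped in `peak_group`-point bins.
#'
#' The printed defaults (slope 0.00001, amplitude 0.6, smooth 50, fit 39,
#' pseudo-Gaussian smoothing, group 2) are the analysis settings for the
#' PVM data. `amp_threshold` is interpreted on a normalized scale by
#' default (`threshold_on = "rms"`): a candidate's smoothed height must
#' exceed `amp_threshold` times the root-mean-square of the smoothed
#' derivative trace, which makes the printed 0.6 independent of the
#' intensity scale while retaining broad, slow transitions whose peak
#' heights are far below the sharpest one. `"max"` normalizes by the trace
#' maximum instead, and `"raw"` compares in raw derivative units.
#'
#' @param slope_threshold Minimum preceding slope of the smoothed signal at
#'   a downward zero crossing (derivative units per point).
#' @param amp_threshold Minimum smoothed peak height, in units set by
#'   `threshold_on`.
#' @param smooth_width Smoothing width in points (forced odd).
#' @param fit_width Number of points around the apex used in the Gaussian
#'   fit.
#' @param smooth_type `"rect"`, `"triangular"` (two rectangular passes) or
#'   `"pseudo-gaussian"` (three passes).
#' @param peak_group Bin size (points) for grouping within the fit window.
#' @param threshold_on `"rms"`, `"max"` or `"raw"`.
#' @return Object of class `peak_find_params`.
#' @export
peak_find_params <- function(slope_threshold = 0.00001,
                             amp_threshold = 0.6,
                             smooth_width = 50,
                             fit_width = 39,
                             smooth_type = c("pseudo-gaussian", "rect", "triangular"),
                             peak_group = 2,
                             threshold_on = c("rms", "max", "raw")) {
  smooth_type <- match.arg(smooth_type)
  threshold_on <- match.arg(threshold_on)
  stopifnot_scalar(slope_threshold, "slope_threshold", nonneg = TRUE)
  stopifnot_scalar(amp_threshold, "amp_threshold", nonneg = TRUE)
  fit_width <- odd_window(fit_width)
  if (fit_width < 3L) stop("fit_width must be >= 3", call. = FALSE)
  structure(
    list(slope_threshold = slope_threshold, amp_threshold = amp_threshold,
         smooth_width = odd_window(smooth_width), fit_width = fit_width,
         smooth_type = smooth_type, peak_group = max(1L, as.integer(peak_group)),
         threshold_on = threshold_on),
    class = "peak_find_params"
  )
}

#' Find and fit peaks in a derivative trace
#'
#' Implements the transition-event detector: smooth, locate downward zero
#' crossings of the smoothed slope, gate by slope and amplitude thresholds,
#' fit each candidate with a Gaussian by least squares on the log of the
#' binned heights of the smoothed signal, and merge candidates whose
#' fitted centers are closer than `fit_width / 2` points (keeping the
#' taller). Reported half-widths therefore include the symmetric smoothing
#' broadening, which leaves the fitted centers unbiased. The fitted center is
#' the transition time; the half-width at half-max of the fitted peak
#' (FWHM / 2) is the transition duration.
#'
#' @param d Numeric \eqn{-dI/dt} trace (see [negated_derivative()]).
#' @param frame_interval Frame interval (s).
#' @param params A [peak_find_params()].
#' @return `data.frame` with columns `time` (s), `half_width` (s),
#'   `amplitude` (raw derivative units, fitted height), sorted by time;
#'   zero rows if no peaks qualify.
#' @export
find_peaks <- function(d, frame_interval, params = peak_find_params()) {
  if (!any(is.finite(d))) stop("derivative trace has no finite values", call. = FALSE)
  ds <- smooth_signal(d, params$smooth_width, params$smooth_type)
  find_peaks_core(d, ds, frame_interval, params)
}

# Core detector operating on a pre-smoothed copy `ds` of `d`.
find_peaks_core <- function(d, ds, frame_interval, params) {
  empty <- data.frame(time = numeric(0), half_width = numeric(0),
                      amplitude = numeric(0))
  n <- length(d)
  sl <- diff(ds)
  # downward zero crossing of the smoothed slope whose drop across the
  # crossing exceeds slope_threshold (slope-threshold semantics of the
  # classic findpeaks routines; a plain preceding-slope test would miss
  # broad peaks at dense sampling, where the slope vanishes at the apex)
  s0 <- sl[-length(sl)]
  s1 <- sl[-1L]
  j <- which(s0 > 0 & s1 <= 0 & (s0 - s1) > params$slope_threshold)
  if (length(j) == 0L) return(empty)
  apex <- j + 1L
  height <- ds[apex]
  denom <- switch(params$threshold_on,
                  rms = sqrt(mean(ds^2)),
                  max = max(ds),
                  raw = 1)
  if (!is.finite(denom) || denom <= 0) return(empty)
  keep <- height / denom > params$amp_threshold
  apex <- apex[keep]
  if (length(apex) == 0L) return(empty)

  half <- (params$fit_width - 1L) %/% 2L
  fits <- lapply(apex, function(a) {
    lo <- max(1L, a - half); hi <- min(n, a + half)
    # fit the detection-smoothed signal: log heights of broad low peaks are
    # far less noise-sensitive there, and the symmetric smoothing leaves
    # peak centers unbiased
    f <- fit_log_gaussian(ds[lo:hi], (lo:hi), params$peak_group)
    # a candidate whose fitted center escapes its own fit window is an
    # artifact of overlapping peaks; drop it
    if (!is.null(f) && abs(f$center - a) > params$fit_width) f <- NULL
    f
  })
  ok <- !vapply(fits, is.null, TRUE)
  fits <- fits[ok]
  if (length(fits) == 0L) return(empty)
  out <- do.call(rbind, fits)
  out <- out[order(out$center), , drop = FALSE]

  # merge fitted centers closer than fit_width/2 points, keep the taller
  min_sep <- params$fit_width / 2
  keep <- rep(TRUE, nrow(out))
  i <- 1L
  while (i < nrow(out)) {
    nxt <- i + 1L
    while (nxt <= nrow(out) && !keep[nxt]) nxt <- nxt + 1L
    if (nxt > nrow(out)) break
    if (out$center[nxt] - out$center[i] < min_sep) {
      if (out$height[nxt] > out$height[i]) {
        keep[i] <- FALSE; i <- nxt
      } else {
        keep[nxt] <- FALSE
      }
    } else {
      i <- nxt
    }
  }
  out <- out[keep, , drop = FALSE]

  data.frame(
    time = (out$center - 1) * frame_interval,
    half_width = out$sigma * sqrt(2 * log(2)) * frame_interval,
    amplitude = out$height
  )
}

# Parabola-on-log Gaussian fit of a peak sampled at integer positions.
# Returns center/sigma (in points) and height, or NULL on failure.
fit_log_gaussian <- function(y, pos, group) {
  if (group > 1L) {
    nb <- length(y) %/% group
    if (nb < 3L) return(NULL)
    idx <- rep(seq_len(nb), each = group)
    y <- tapply(y[seq_along(idx)], idx, mean)
    pos <- tapply(pos[seq_along(idx)], idx, mean)
  }
  keep <- is.finite(y) & y > 0
  if (sum(keep) < 3L) return(NULL)
  y <- y[keep]; pos <- pos[keep]
  t0 <- mean(pos)
  x <- pos - t0
  X <- cbind(1, x, x^2)
  co <- tryCatch(stats::lm.fit(X, log(y))$coefficients, error = function(e) NULL)
  if (is.null(co) || anyNA(co) || co[3] >= 0) return(NULL)
  c2 <- co[3]; c1 <- co[2]; c0 <- co[1]
  data.frame(center = t0 - c1 / (2 * c2),
             sigma = sqrt(-1 / (2 * c2)),
             height = exp(c0 - c1^2 / (4 * c2)))
}

#' Detect transition events for every pixel of a video
#'
#' Runs the full per-trace pipeline — trace smoothing, negated derivative,
#' derivative smoothing, peak finding and Gaussian fitting — for every
#' pixel (or superpixel) of a video. Per-pixel fit failures are recorded as
#' missing detections; the run never aborts on a single trace.
#'
#' @param video An [intensity_video()] (typically an ROI or a superpixel
#'   resampling of one).
#' @param trace_smooth_seconds Sliding-window smoothing of the intensity
#'   traces (s), default 15.2.
#' @param derivative_smooth_seconds Extra smoothing of the derivative (s),
#'   default 7.78.
#' @param params A [peak_find_params()].
#' @return Object of class `pixel_transition_set`: list with `events` (a
#'   `data.frame` with columns `pixel`, `row`, `col`, `time`, `half_width`,
#'   `amplitude`, sorted by pixel then time) and `n_events` (per-pixel
#'   event counts), plus the geometry and parameters used.
#' @export
detect_pixel_transitions <- function(video,
                                     trace_smooth_seconds = 15.2,
                                     derivative_smooth_seconds = 7.78,
                                     params = peak_find_params()) {
  d <- dim(video$data)
  if (d[1] < 50L) stop("video too short for transition detection", call. = FALSE)
  dt <- video$frame_interval
  m <- pixel_traces(video)
  m <- roll_mean_mat(m, odd_window(trace_smooth_seconds / dt))
  m <- -central_diff_mat(m) / dt
  if (derivative_smooth_seconds > 0) {
    m <- roll_mean_mat(m, odd_window(derivative_smooth_seconds / dt))
  }
  ms <- smooth_signal_mat(m, params$smooth_width, params$smooth_type)

  n_px <- ncol(m)
  res <- vector("list", n_px)
  for (i in seq_len(n_px)) {
    ev <- tryCatch(find_peaks_core(m[, i], ms[, i], dt, params),
                   error = function(e) NULL)
    if (!is.null(ev) && nrow(ev) > 0L) {
      ev$pixel <- i
      res[[i]] <- ev
    }
  }
  res <- res[!vapply(res, is.null, TRUE)]
  events <- if (length(res)) {
    do.call(rbind, res)
  } else {
    data.frame(time = numeric(0), half_width = numeric(0),
               amplitude = numeric(0), pixel = integer(0))
  }
  h <- d[2]
  events$row <- ((events$pixel - 1L) %% h) + 1L
  events$col <- ((events$pixel - 1L) %/% h) + 1L
  events <- events[order(events$pixel, events$time),
                   c("pixel", "row", "col", "time", "half_width", "amplitude")]
  rownames(events) <- NULL
  counts <- integer(n_px)
  if (nrow(events)) {
    tab <- table(events$pixel)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  structure(
    list(events = events, n_events = counts, height = d[2], width = d[3],
         frame_interval = dt, params = params),
    class = "pixel_transition_set"
  )
}

#' @export
print.pixel_transition_set <- function(x, ...) {
  cat(sprintf("<pixel_transition_set> %d events over %d x %d pixels (modal count %s)\n",
              nrow(x$events), x$height, x$width,
              if (length(x$n_events)) names(sort(table(x$n_events), decreasing = TRUE))[1] else "0"))
  invisible(x)
}

#' Start/end intensity summary of a trace
#'
#' The initial and final levels are the means of the first and last 5\% of
#' frames; the fractional loss is `1 - final/initial`. A complete
#' multiphasic transition with designed amplitudes summing to 0.5 loses
#' 50\% of the starting intensity.
#'
#' @param trace Numeric intensity trace (length >= 2).
#' @param edge_fraction Fraction of frames averaged at each end.
#' @return List with `initial`, `final`, `fractional_loss`.
#' @export
trace_summary <- function(trace, edge_fraction = 0.05) {
  n <- length(trace)
  if (n < 2L) stop("trace must have at least 2 points", call. = FALSE)
  k <- max(1L, floor(edge_fraction * n))
  initial <- mean(trace[seq_len(k)])
  final <- mean(trace[(n - k + 1L):n])
  if (!is.finite(initial) || initial == 0) {
    stop("initial intensity is zero; fractional loss undefined", call. = FALSE)
  }
  list(initial = initial, final = final, fractional_loss = 1 - final / initial)
}
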