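#' Parameters of a synthetic multiphasic birefringence decay
#'
#' Describes the designed per-pixel transmitted-intensity trace of a crystal
#' undergoing a sequence of solid-solid lattice transitions under crossed
#' polarizers. The trace is a baseline intensity from which each transition
#' removes a logistic (sigmoidal) fraction:
#' \deqn{I(t) = I_0 \left[1 - \sum_k a_k S((t - t_k)/\tau_k)\right] + \epsilon(t)}
#' with \eqn{S(u) = 1/(1 + e^{-u})} and i.i.d. Gaussian camera noise
#' \eqn{\epsilon}. The default transition set (T1, T2a, T2b, T3) places the
#' sharp first transition T1 at 227 s and removes 50\% of the baseline in
#' total, matching the kinetics the pipeline is designed to quantify.
#'
#' @param baseline_intensity Baseline intensity \eqn{I_0} (arbitrary camera
#'   units, default 200).
#' @param transitions `data.frame` with columns `label`, `center_time` (s),
#'   `tau` (s, logistic timescale) and `amplitude` (fraction of \eqn{I_0}
#'   lost). Center times must be strictly increasing, `tau > 0`, and the
#'   amplitudes must sum into (0, 1].
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units). Default 1\% of the baseline.
#' @return An object of class `trace_params`.
#' @seealso [generate_trace()], [video_params()]
#' @export
trace_params <- function(baseline_intensity = 200,
                         transitions = default_transitions(),
                         noise_sd = 0.01 * baseline_intensity) {
  stopifnot_scalar(baseline_intensity, "baseline_intensity", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  tr <- as.data.frame(transitions, stringsAsFactors = FALSE)
  need <- c("label", "center_time", "tau", "amplitude")
  if (!all(need %in% names(tr))) {
    stop("`transitions` needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(tr) < 1L) stop("at least one transition is required", call. = FALSE)
  if (any(tr$tau <= 0)) stop("all `tau` must be > 0", call. = FALSE)
  if (any(tr$amplitude <= 0)) stop("all amplitudes must be > 0", call. = FALSE)
  if (is.unsorted(tr$center_time, strictly = TRUE)) {
    stop("transition center times must be strictly increasing", call. = FALSE)
  }
  total <- sum(tr$amplitude)
  if (total <= 0 || total > 1) {
    stop("transition amplitudes must sum into (0, 1]", call. = FALSE)
  }
  structure(
    list(baseline_intensity = baseline_intensity, transitions = tr,
         noise_sd = noise_sd, total_loss_fraction = total),
    class = "trace_params"
  )
}

#' Default transition table for the synthetic decay
#'
#' T1 is sharp (tau = 1 s) and centered at 227 s; T2a/T2b/T3 follow at
#' +120/+150/+260 s with timescales 4/6/8 s. Amplitudes 0.20/0.10/0.10/0.10
#' sum to the designed 50\% total loss.
#'
#' @param t1_center Center time of T1 in seconds.
#' @return `data.frame` with one row per transition.
#' @export
default_transitions <- function(t1_center = 227) {
  data.frame(
    label = c("T1", "T2a", "T2b", "T3"),
    center_time = t1_center + c(0, 120, 150, 260),
    tau = c(1, 4, 6, 8),
    amplitude = c(0.20, 0.10, 0.10, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Generate one synthetic intensity trace
#'
#' Evaluates the multiphasic logistic decay of [trace_params()] on a time
#' grid and adds i.i.d. Gaussian noise.
#'
#' @param params A [trace_params()] object.
#' @param times Increasing, uniformly spaced sample times (s).
#' @param seed Optional integer seed for the noise; the caller's RNG state
#'   is left untouched.
#' @return Numeric vector of intensities, same length as `times`.
#' @examples
#' tp <- trace_params(noise_sd = 0)
#' tr <- generate_trace(tp, seq(0, 600, by = 0.39))
#' @export
generate_trace <- function(params, times, seed = NULL) {
  if (!inherits(params, "trace_params")) params <- do.call(trace_params, params)
  if (length(times) < 2L || is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be increasing", call. = FALSE)
  }
  dt <- diff(times)
  if (max(dt) - min(dt) > 1e-8 * max(dt)) {
    stop("`times` must be uniformly spaced", call. = FALSE)
  }
  tr <- params$transitions
  drop <- rep(0, length(times))
  for (k in seq_len(nrow(tr))) {
    drop <- drop + tr$amplitude[k] * stats::plogis((times - tr$center_time[k]) / tr$tau[k])
  }
  y <- params$baseline_intensity * (1 - drop)
  if (params$noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(times), 0, params$noise_sd))
  }
  y
}

#' Parameters of a synthetic PVM video
#'
#' Extends [trace_params()] to a full region of interest: every pixel gets
#' the same designed transition sequence, with per-pixel transition-time
#' jitter (Gaussian, sd `jitter_sd[k]` for transition k) and, optionally, a
#' deterministic spatial offset field:
#' \describe{
#'   \item{`synchronous`}{no field; jitter only. The default `jitter_sd` of
#'     1.5 s for T1 makes ~90\% of pixels transition within a 5-s window
#'     (erf(2.5 / (1.5 sqrt(2))) = 0.904).}
#'   \item{`gradient`}{adds a left-to-right linear ramp spanning
#'     `gradient_span` seconds edge to edge (a negative control that breaks
#'     superpixel-scale synchrony).}
#'   \item{`nucleation`}{adds a radial ramp growing from the ROI corner,
#'     also spanning `gradient_span` seconds.}
#' }
#'
#' @param trace_params A [trace_params()] object.
#' @param height,width ROI size in pixels.
#' @param n_frames Number of frames; together with `frame_interval` the
#'   video must extend at least 5 max(tau) past the last transition center.
#' @param frame_interval Frame interval in seconds. The default 15.2/39 =
#'   0.38974 s reproduces a 39-step 15.2-s smoothing window.
#' @param jitter_sd Per-transition jitter sd (s); recycled to the number of
#'   transitions.
#' @param spatial_mode One of `"synchronous"`, `"gradient"`, `"nucleation"`.
#' @param gradient_span Edge-to-edge span (s) of the deterministic field for
#'   the non-synchronous modes.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `video_params`.
#' @export
video_params <- function(trace_params = phasekin::trace_params(),
                         height = 180, width = 180,
                         n_frames = 1550, frame_interval = 15.2 / 39,
                         jitter_sd = 1.5,
                         spatial_mode = c("synchronous", "gradient", "nucleation"),
                         gradient_span = 10,
                         seed = 1L) {
  spatial_mode <- match.arg(spatial_mode)
  if (!inherits(trace_params, "trace_params")) {
    trace_params <- do.call(phasekin::trace_params, trace_params)
  }
  stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  stopifnot_scalar(gradient_span, "gradient_span", nonneg = TRUE)
  height <- as.integer(height); width <- as.integer(width)
  n_frames <- as.integer(n_frames)
  if (height < 1L || width < 1L || n_frames < 2L) {
    stop("invalid video geometry", call. = FALSE)
  }
  tr <- trace_params$transitions
  jitter_sd <- rep_len(as.numeric(jitter_sd), nrow(tr))
  if (any(jitter_sd < 0)) stop("jitter_sd must be >= 0", call. = FALSE)
  span <- (n_frames - 1L) * frame_interval
  if (span <= max(tr$center_time) + 5 * max(tr$tau)) {
    stop("video too short: it must extend 5*max(tau) past the last transition",
         call. = FALSE)
  }
  structure(
    list(trace_params = trace_params, height = height, width = width,
         n_frames = n_frames, frame_interval = frame_interval,
         jitter_sd = jitter_sd, spatial_mode = spatial_mode,
         gradient_span = gradient_span, seed = as.integer(seed)),
    class = "video_params"
  )
}

# Deterministic spatial offset field (seconds) for a video_params object.
spatial_offset_field <- function(p) {
  switch(p$spatial_mode,
    synchronous = matrix(0, p$height, p$width),
    gradient = {
      ramp <- if (p$width > 1L) seq(0, p$gradient_span, length.out = p$width) else 0
      matrix(ramp, p$height, p$width, byrow = TRUE)
    },
    nucleation = {
      x <- matrix(seq_len(p$width) - 1L, p$height, p$width, byrow = TRUE)
      y <- matrix(seq_len(p$height) - 1L, p$height, p$width)
      r <- sqrt(x^2 + y^2)
      p$gradient_span * r / max(r)
    }
  )
}

#' Generate a synthetic PVM video with ground truth
#'
#' Renders the per-pixel multiphasic decay of [video_params()] into an
#' [intensity_video()] stack and returns the per-pixel true transition
#' times alongside.
#'
#' Pixels are indexed column-major (pixel `i` of an H x W ROI is row
#' `((i-1) mod H) + 1`, column `((i-1) div H) + 1`), 0-based origin at the
#' top-left corner of the ROI.
#'
#' @param params A [video_params()] object.
#' @return List with elements `video` (an [intensity_video()]) and `truth`,
#'   a `data.frame` with columns `pixel`, `row`, `col`, `label`,
#'   `true_time` (s) holding the jittered per-pixel transition centers.
#' @export
generate_video <- function(params) {
  if (!inherits(params, "video_params")) params <- do.call(video_params, params)
  p <- params
  tp <- p$trace_params
  tr <- tp$transitions
  n_px <- p$height * p$width
  n_tr <- nrow(tr)
  times <- (seq_len(p$n_frames) - 1L) * p$frame_interval
  field <- as.vector(spatial_offset_field(p))

  centers <- with_seed(p$seed, {
    jit <- matrix(stats::rnorm(n_px * n_tr), n_px, n_tr)
    jit <- sweep(jit, 2L, p$jitter_sd, `*`)
    sweep(jit, 2L, tr$center_time, `+`) + field
  })

  drop <- matrix(0, p$n_frames, n_px)
  for (k in seq_len(n_tr)) {
    u <- outer(times, centers[, k], `-`) / tr$tau[k]
    drop <- drop + tr$amplitude[k] * stats::plogis(u)
  }
  data <- tp$baseline_intensity * (1 - drop)
  rm(drop)
  if (tp$noise_sd > 0) {
    # separate stream from the jitter so noise does not shift the truth
    data <- data + with_seed(p$seed + 1L,
      matrix(stats::rnorm(length(data), 0, tp$noise_sd), nrow(data), ncol(data)))
  }
  dim(data) <- c(p$n_frames, p$height, p$width)
  video <- intensity_video(data, frame_interval = p$frame_interval)

  px <- seq_len(n_px)
  truth <- data.frame(
    pixel = rep(px, n_tr),
    row = rep(((px - 1L) %% p$height) + 1L, n_tr),
    col = rep(((px - 1L) %/% p$height) + 1L, n_tr),
    label = rep(tr$label, each = n_px),
    true_time = as.vector(centers),
    stringsAsFactors = FALSE
  )
  list(video = video, truth = truth, params = p)
}
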