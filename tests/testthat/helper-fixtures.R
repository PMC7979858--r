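# Shared fixtures: small synthetic inputs built in code at test time.

DT <- 15.2 / 39   # frame interval implied by a 39-step 15.2-s window

single_transition_params <- function(center = 227, tau = 1, amplitude = 0.2,
                                     noise_sd = 0, baseline = 200) {
  trace_params(
    baseline_intensity = baseline,
    transitions = data.frame(label = "T1", center_time = center, tau = tau,
                             amplitude = amplitude),
    noise_sd = noise_sd
  )
}

# Cache expensive fixtures across tests within one run.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small but fully featured synchronous video (all four designed
# transitions, default jitter and noise), used by several test files.
small_video <- function() {
  fixture("small_video", function() {
    generate_video(video_params(height = 12, width = 12, n_frames = 1550,
                                seed = 42))
  })
}

# Default per-trace detection chain (smooth -> derivative -> peaks).
find_trace_events <- function(y, dt = DT, params = peak_find_params()) {
  s <- smooth_trace(y, 15.2, dt)
  d <- negated_derivative(s, dt, 7.78)
  find_peaks(d, dt, params)
}

# Brute-force circular 2D autocorrelation by shift-multiply-sum.
brute_acf <- function(z) {
  z <- z - mean(z)
  h <- nrow(z); w <- ncol(z)
  out <- matrix(0, h, w)
  for (dy in 0:(h - 1)) for (dx in 0:(w - 1)) {
    shifted <- z[((seq_len(h) - 1 + dy) %% h) + 1, ((seq_len(w) - 1 + dx) %% w) + 1]
    out[dy + 1, dx + 1] <- sum(z * shifted)
  }
  out / out[1, 1]
}

# Center a raw (lag-0 first) ACF the same way autocorrelate() does.
center_acf <- function(a) {
  h <- nrow(a); w <- ncol(a)
  ctr <- c(floor(h / 2) + 1L, floor(w / 2) + 1L)
  a[c((h - ctr[1] + 2L):h, 1L:(h - ctr[1] + 1L)),
    c((w - ctr[2] + 2L):w, 1L:(w - ctr[2] + 1L)), drop = FALSE]
}
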