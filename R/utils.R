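# Internal numeric helpers shared across modules.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Round a window length (in samples) to the nearest odd integer >= 1.
odd_window <- function(n) {
  n <- as.integer(round(n))
  if (n < 1L) n <- 1L
  if (n %% 2L == 0L) n <- n + 1L
  n
}

# Centered moving average with shrinking (truncated) windows at the edges.
# `w` must be odd. Uses cumulative sums; R's cumsum accumulates in long
# double so the result matches a brute-force windowed mean to ~1e-12.
roll_mean <- function(x, w) {
  n <- length(x)
  if (w >= 2L * n) stop("smoothing window longer than the trace", call. = FALSE)
  if (w <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Column-wise version of roll_mean for a T x N trace matrix.
roll_mean_mat <- function(m, w) {
  n <- nrow(m)
  if (w >= 2L * n) stop("smoothing window longer than the trace", call. = FALSE)
  if (w <= 1L) return(m)
  h <- (w - 1L) %/% 2L
  cs <- rbind(0, apply(m, 2L, cumsum))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

# Pseudo-Gaussian smoothing: three passes of the rectangular window.
smooth_signal <- function(x, width, type = c("pseudo-gaussian", "rect", "triangular")) {
  type <- match.arg(type)
  w <- odd_window(width)
  passes <- switch(type, rect = 1L, triangular = 2L, `pseudo-gaussian` = 3L)
  for (p in seq_len(passes)) x <- roll_mean(x, w)
  x
}

smooth_signal_mat <- function(m, width, type = c("pseudo-gaussian", "rect", "triangular")) {
  type <- match.arg(type)
  w <- odd_window(width)
  passes <- switch(type, rect = 1L, triangular = 2L, `pseudo-gaussian` = 3L)
  for (p in seq_len(passes)) m <- roll_mean_mat(m, w)
  m
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}
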