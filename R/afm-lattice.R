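#' AFM topograph
#'
#' A 2D height map in nm with its nm-per-pixel calibration, the unit of
#' analysis for surface-lattice measurement.
#'
#' @param heights Numeric matrix (rows = y, columns = x), finite.
#' @param nm_per_px Calibration (nm per pixel).
#' @param index Optional acquisition (serial image) index.
#' @param time Optional acquisition time (s).
#' @param label Optional phase/region label.
#' @return Object of class `topograph`.
#' @export
topograph <- function(heights, nm_per_px, index = NA_integer_,
                      time = NA_real_, label = NA_character_) {
  if (!is.matrix(heights) || !all(is.finite(heights))) {
    stop("`heights` must be a finite numeric matrix", call. = FALSE)
  }
  stopifnot_scalar(nm_per_px, "nm_per_px", positive = TRUE)
  structure(list(heights = heights, nm_per_px = nm_per_px,
                 index = index, time = time, label = label),
            class = "topograph")
}

#' @export
print.topograph <- function(x, ...) {
  cat(sprintf("<topograph> %d x %d px at %.4f nm/px (%.0f x %.0f nm)\n",
              nrow(x$heights), ncol(x$heights), x$nm_per_px,
              nrow(x$heights) * x$nm_per_px, ncol(x$heights) * x$nm_per_px))
  invisible(x)
}

#' Line-by-line first-order flattening
#'
#' Subtracts a least-squares straight line from every scan line (image
#' row), the standard first-order flatten that removes sample tilt
#' artifacts from raster-scanned AFM images. Idempotent.
#'
#' @param topo A [topograph()] with at least 3 columns.
#' @return Flattened [topograph()].
#' @export
flatten_lines <- function(topo) {
  z <- topo$heights
  w <- ncol(z)
  if (w < 3L) stop("need at least 3 pixels per line", call. = FALSE)
  x <- seq_len(w) - (w + 1) / 2          # centered abscissa
  sxx <- sum(x^2)
  slope <- drop(z %*% x) / sxx
  z <- z - outer(slope, x) - rowMeans(z)
  out <- topo
  out$heights <- z
  out
}

#' Denoise a topograph
#'
#' Two modes mirror standard scanning-probe image processing:
#' \describe{
#'   \item{`fft_lowpass`}{zeroes all spatial frequencies above
#'     `cutoff_frac` of the Nyquist frequency and inverse-transforms.}
#'   \item{`correlation_average`}{registers unit-cell-sized patches against
#'     a reference patch by cross-correlation, averages them, and writes
#'     the average back at every registered position (overlaps averaged);
#'     random noise cancels while the periodic motif is retained.}
#' }
#'
#' @param topo A [topograph()].
#' @param mode `"fft_lowpass"` or `"correlation_average"`.
#' @param cutoff_frac Low-pass cutoff as a fraction of Nyquist, in (0, 1].
#' @param patch_px Patch side for correlation averaging (px); default
#'   roughly 1.5 designed cells at the default calibration.
#' @param rel_threshold Correlation peaks below this fraction of the
#'   maximum are not used as patch positions.
#' @return Denoised [topograph()].
#' @export
denoise <- function(topo, mode = c("fft_lowpass", "correlation_average"),
                    cutoff_frac = 0.5, patch_px = 36, rel_threshold = 0.5) {
  mode <- match.arg(mode)
  z <- topo$heights
  out <- topo
  if (mode == "fft_lowpass") {
    if (cutoff_frac <= 0 || cutoff_frac > 1) {
      stop("cutoff must lie in (0, Nyquist]", call. = FALSE)
    }
    h <- nrow(z); w <- ncol(z)
    fy <- fft_freq(h); fx <- fft_freq(w)
    r <- sqrt(outer(fy^2, fx^2, `+`))
    mask <- r <= cutoff_frac * 0.5
    F <- stats::fft(z)
    out$heights <- Re(stats::fft(F * mask, inverse = TRUE)) / (h * w)
  } else {
    out$heights <- correlation_average(z, patch_px, rel_threshold)
  }
  out
}

fft_freq <- function(n) {
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  if (n == 1L) k <- 0
  k[seq_len(n)] / n
}

# Correlation averaging: register patch-sized windows against a central
# reference patch via circular cross-correlation and average them.
correlation_average <- function(z, patch_px, rel_threshold) {
  h <- nrow(z); w <- ncol(z)
  patch_px <- min(as.integer(patch_px), h - 1L, w - 1L)
  zc <- z - mean(z)
  r0 <- (h - patch_px) %/% 2L + 1L
  c0 <- (w - patch_px) %/% 2L + 1L
  ref <- zc[r0:(r0 + patch_px - 1L), c0:(c0 + patch_px - 1L)]
  tpl <- matrix(0, h, w)
  tpl[seq_len(patch_px), seq_len(patch_px)] <- ref - mean(ref)
  cc <- Re(stats::fft(Conj(stats::fft(tpl)) * stats::fft(zc), inverse = TRUE)) / (h * w)
  peaks <- local_maxima(cc, wrap = TRUE)
  vals <- cc[peaks]
  keep <- vals >= rel_threshold * max(vals)
  pos <- which(peaks & cc >= rel_threshold * max(vals), arr.ind = TRUE)
  # positions are top-left corners (1-based) of registered patches
  pos <- pos[pos[, 1] + patch_px - 1L <= h & pos[, 2] + patch_px - 1L <= w, ,
             drop = FALSE]
  if (nrow(pos) == 0L) return(z)
  acc <- matrix(0, patch_px, patch_px)
  for (i in seq_len(nrow(pos))) {
    acc <- acc + z[pos[i, 1]:(pos[i, 1] + patch_px - 1L),
                   pos[i, 2]:(pos[i, 2] + patch_px - 1L)]
  }
  avg <- acc / nrow(pos)
  num <- matrix(0, h, w); den <- matrix(0, h, w)
  for (i in seq_len(nrow(pos))) {
    rr <- pos[i, 1]:(pos[i, 1] + patch_px - 1L)
    ccid <- pos[i, 2]:(pos[i, 2] + patch_px - 1L)
    num[rr, ccid] <- num[rr, ccid] + avg
    den[rr, ccid] <- den[rr, ccid] + 1
  }
  ifelse(den > 0, num / pmax(den, 1), z)
}

# Logical matrix marking strict local maxima over the 8-neighborhood.
local_maxima <- function(m, wrap = FALSE) {
  h <- nrow(m); w <- ncol(m)
  sh <- function(dr, dc) {
    if (wrap) {
      ri <- ((seq_len(h) - 1L + dr) %% h) + 1L
      ci <- ((seq_len(w) - 1L + dc) %% w) + 1L
      m[ri, ci, drop = FALSE]
    } else {
      out <- matrix(-Inf, h, w)
      rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
      ok_r <- rs >= 1L & rs <= h; ok_c <- cs >= 1L & cs <= w
      out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c], drop = FALSE]
      out
    }
  }
  res <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    res <- res & (m > sh(dr, dc) | (m == sh(dr, dc) & (dr > 0L | (dr == 0L & dc > 0L))))
  }
  res
}

#' 2D autocorrelation map of a topograph
#'
#' Computes the normalized circular (periodic) autocorrelation via the
#' frequency domain: the image is mean-subtracted, transformed, and the
#' inverse transform of its power spectrum is normalized to 1 at zero lag.
#' Lattice periodicity produces peaks at the lattice-vector lags. The map
#' is returned centered (zero lag at `center`), and is exactly
#' centro-symmetric.
#'
#' @param topo A [topograph()] (or plain matrix plus `nm_per_px`).
#' @param nm_per_px Calibration if `topo` is a matrix.
#' @return Object of class `autocorrelation_map`: `acf` matrix, `center`
#'   `c(row, col)` of the zero lag, `nm_per_px`.
#' @export
autocorrelate <- function(topo, nm_per_px = NULL) {
  if (inherits(topo, "topograph")) {
    z <- topo$heights; nm_per_px <- topo$nm_per_px
  } else {
    z <- topo
    if (is.null(nm_per_px)) stop("nm_per_px required for matrix input", call. = FALSE)
  }
  z <- z - mean(z)
  v <- mean(z^2)
  if (v == 0) stop("constant image: autocorrelation undefined", call. = FALSE)
  h <- nrow(z); w <- ncol(z)
  F <- stats::fft(z)
  acf <- Re(stats::fft(Mod(F)^2, inverse = TRUE)) / (h * w)
  acf <- acf / acf[1, 1]
  ctr <- c(floor(h / 2) + 1L, floor(w / 2) + 1L)
  acf <- acf[c((h - ctr[1] + 2L):h, 1L:(h - ctr[1] + 1L)),
             c((w - ctr[2] + 2L):w, 1L:(w - ctr[2] + 1L)), drop = FALSE]
  structure(list(acf = acf, center = ctr, nm_per_px = nm_per_px),
            class = "autocorrelation_map")
}

#' Measure the surface unit cell from an autocorrelation map
#'
#' Automates the manual prominent-peak reading of an ACF: local maxima off
#' the origin are ranked by height, refined to sub-pixel positions by a
#' quadratic fit to their 3x3 neighborhood, and the two shortest
#' non-collinear lattice vectors (inter-vector angle > 20 deg) inside the
#' spacing window are taken as the in-plane cell. Lengths are reported
#' sorted (`a_len <= c_len`) with the inter-vector angle in degrees.
#'
#' @param acf An [autocorrelate()] result.
#' @param min_spacing_nm,max_spacing_nm Spacing window for acceptable
#'   lattice vectors.
#' @param min_angle Collinearity guard (deg).
#' @param rel_prominence Peaks below this fraction of the strongest
#'   off-origin peak in the window are ignored (suppresses noise ripples
#'   between lattice peaks).
#' @return Object of class `unit_cell_measurement`: `ok`, `a_len`, `c_len`
#'   (nm), `angle` (deg), `prominences`, `vectors_px`, `method`. If fewer
#'   than two acceptable peaks exist, `ok = FALSE` with `NA` lengths (a
#'   measurement-failure result, not an error).
#' @export
measure_unit_cell <- function(acf, min_spacing_nm = 2, max_spacing_nm = 20,
                              min_angle = 20, rel_prominence = 0.25) {
  m <- acf$acf
  npp <- acf$nm_per_px
  ctr <- c(floor(nrow(m) / 2) + 1L, floor(ncol(m) / 2) + 1L)
  peaks <- which(local_maxima(m), arr.ind = TRUE)
  dy <- peaks[, 1] - ctr[1]
  dx <- peaks[, 2] - ctr[2]
  r_nm <- sqrt(dy^2 + dx^2) * npp
  upper <- dy > 0 | (dy == 0 & dx > 0)       # one of each +/- pair
  sel <- upper & r_nm >= min_spacing_nm & r_nm <= max_spacing_nm &
    peaks[, 1] > 1 & peaks[, 1] < nrow(m) & peaks[, 2] > 1 & peaks[, 2] < ncol(m)
  fail <- structure(list(ok = FALSE, a_len = NA_real_, c_len = NA_real_,
                         angle = NA_real_, prominences = numeric(0),
                         vectors_px = NULL, method = "acf"),
                    class = "unit_cell_measurement")
  if (sum(sel) < 2L) return(fail)
  peaks <- peaks[sel, , drop = FALSE]
  heights <- m[peaks]
  prom <- heights >= rel_prominence * max(heights)
  peaks <- peaks[prom, , drop = FALSE]
  heights <- heights[prom]
  if (length(heights) < 2L) return(fail)
  ord <- order(heights, decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]
  heights <- heights[ord]

  refined <- t(apply(peaks, 1L, function(pk) refine_peak(m, pk[1], pk[2])))
  vy <- refined[, 1] - ctr[1]
  vx <- refined[, 2] - ctr[2]
  len <- sqrt(vy^2 + vx^2) * npp
  ang <- atan2(vy, vx) * 180 / pi

  i1 <- which.min(len)
  sep <- abs(ang - ang[i1]) %% 180
  sep <- pmin(sep, 180 - sep)
  cand2 <- which(sep > min_angle & sep < 180 - min_angle)
  if (length(cand2) == 0L) return(fail)
  i2 <- cand2[which.min(len[cand2])]

  l1 <- len[i1]; l2 <- len[i2]
  between <- sep[i2]
  out <- list(ok = TRUE,
              a_len = min(l1, l2), c_len = max(l1, l2),
              angle = between,
              prominences = heights[c(i1, i2)],
              vectors_px = rbind(c(vx[i1], vy[i1]), c(vx[i2], vy[i2])),
              method = "acf")
  structure(out, class = "unit_cell_measurement")
}

#' @export
print.unit_cell_measurement <- function(x, ...) {
  if (!x$ok) {
    cat("<unit_cell_measurement> FAILED (fewer than 2 acceptable peaks)\n")
  } else {
    cat(sprintf("<unit_cell_measurement> a = %.2f nm, c = %.2f nm, angle = %.1f deg\n",
                x$a_len, x$c_len, x$angle))
  }
  invisible(x)
}

# Sub-pixel refinement: 2D quadratic fit over the 3x3 neighborhood.
refine_peak <- function(m, r, c) {
  if (r <= 1L || r >= nrow(m) || c <= 1L || c >= ncol(m)) return(c(r, c))
  z <- m[(r - 1L):(r + 1L), (c - 1L):(c + 1L)]
  dzdy <- (z[3, 2] - z[1, 2]) / 2
  dzdx <- (z[2, 3] - z[2, 1]) / 2
  dyy <- z[3, 2] - 2 * z[2, 2] + z[1, 2]
  dxx <- z[2, 3] - 2 * z[2, 2] + z[2, 1]
  dxy <- (z[3, 3] - z[3, 1] - z[1, 3] + z[1, 1]) / 4
  H <- matrix(c(dyy, dxy, dxy, dxx), 2, 2)
  det_h <- dyy * dxx - dxy^2
  if (!is.finite(det_h) || det_h <= 0 || dyy >= 0) return(c(r, c))
  off <- -solve(H, c(dzdy, dzdx))
  off <- pmin(pmax(off, -1), 1)
  c(r + off[1], c + off[2])
}

#' Measure unit cells for rectangular sub-regions
#'
#' For a mixed-phase topograph, crops each rectangle, applies line-by-line
#' flattening, autocorrelates, and measures the unit cell per region.
#' Regions that fail (too small, too few peaks) yield a failure result
#' while the others proceed.
#'
#' @param topo A [topograph()].
#' @param regions List of rectangles: each a list with `rows` and `cols`
#'   (`c(first, last)`, 1-based inclusive), or [region_spec()] objects.
#' @param ... Passed to [measure_unit_cell()].
#' @return List of `unit_cell_measurement`, one per region.
#' @export
measure_regions <- function(topo, regions, ...) {
  lapply(regions, function(r) {
    tryCatch({
      crop <- topo
      crop$heights <- topo$heights[r$rows[1]:r$rows[2], r$cols[1]:r$cols[2],
                                   drop = FALSE]
      measure_unit_cell(autocorrelate(flatten_lines(crop)), ...)
    }, error = function(e) {
      structure(list(ok = FALSE, a_len = NA_real_, c_len = NA_real_,
                     angle = NA_real_, prominences = numeric(0),
                     vectors_px = NULL, method = "acf",
                     message = conditionMessage(e)),
                class = "unit_cell_measurement")
    })
  })
}

#' Phase-labeled c-axis time series
#'
#' Assigns each unit-cell measurement the phase of the nearest reference
#' c-axis length (defaults: AUC 9.3 nm, TUC1 7.9 nm, TUC2 12.4 nm), within
#' a maximum deviation of `max_dev_nm`; measurements further than that are
#' labeled `"intermediate"`, failed measurements `"gap"`. With an empty
#' reference set all measurements are `"unassigned"`.
#'
#' @param measurements `data.frame` with columns `index` and `c_len`
#'   (optionally `time`), or a list of `unit_cell_measurement` (indices
#'   taken in order).
#' @param references Named numeric vector of reference c-axis lengths (nm).
#' @param max_dev_nm Maximum |c - reference| for assignment.
#' @return `data.frame` with columns `index`, `time` (if given), `c_len`,
#'   `phase`, ordered by index; class `lattice_time_series`.
#' @export
caxis_timeseries <- function(measurements,
                             references = c(AUC = 9.3, TUC1 = 7.9, TUC2 = 12.4),
                             max_dev_nm = 1.0) {
  if (is.list(measurements) && !is.data.frame(measurements) &&
      all(vapply(measurements, inherits, TRUE, "unit_cell_measurement"))) {
    measurements <- data.frame(
      index = seq_along(measurements),
      c_len = vapply(measurements, function(x) if (x$ok) x$c_len else NA_real_, 0))
  }
  df <- as.data.frame(measurements)
  if (!all(c("index", "c_len") %in% names(df))) {
    stop("`measurements` needs `index` and `c_len`", call. = FALSE)
  }
  if (nrow(df) < 1L) stop("need at least one measurement", call. = FALSE)
  df <- df[order(df$index), , drop = FALSE]
  df$phase <- vapply(df$c_len, function(cl) {
    if (is.na(cl)) return("gap")
    if (length(references) == 0L) return("unassigned")
    d <- abs(references - cl)
    if (min(d) <= max_dev_nm) names(references)[which.min(d)] else "intermediate"
  }, "")
  rownames(df) <- NULL
  class(df) <- c("lattice_time_series", "data.frame")
  df
}
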