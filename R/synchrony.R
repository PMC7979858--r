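#' Superpixel sampling scheme
#'
#' Block-averaging plan for testing scale invariance of the transition
#' statistics: each sampling area (block side, px) must divide the ROI side
#' exactly. The default areas 1, 3, 6, 9, 15, 30, 45 and 90 px on a 180-px
#' ROI give 180, 60, 30, 20, 12, 6, 4 and 2 superpixels per side.
#'
#' @param roi_side ROI side length (px).
#' @param sampling_areas Integer block sides.
#' @return Object of class `superpixel_scheme` with a `superpixels_per_side`
#'   column.
#' @export
superpixel_scheme <- function(roi_side = 180,
                              sampling_areas = c(1, 3, 6, 9, 15, 30, 45, 90)) {
  roi_side <- as.integer(roi_side)
  sampling_areas <- as.integer(sampling_areas)
  if (any(roi_side %% sampling_areas != 0L)) {
    stop("every sampling area must divide the ROI side exactly", call. = FALSE)
  }
  structure(
    list(roi_side = roi_side, sampling_areas = sampling_areas,
         superpixels_per_side = roi_side %/% sampling_areas),
    class = "superpixel_scheme"
  )
}

#' Resample a video into superpixels
#'
#' Replaces each `block_side x block_side` block of pixels by its
#' arithmetic mean, frame by frame, yielding a smaller video of superpixel
#' traces. The mean of the superpixel traces equals the grand mean of the
#' pixel traces exactly.
#'
#' @param video An [intensity_video()] whose ROI sides are divisible by
#'   `block_side`.
#' @param block_side Sampling-area side (px).
#' @return An [intensity_video()] with `side / block_side` superpixels per
#'   side.
#' @export
resample_superpixels <- function(video, block_side) {
  block_side <- as.integer(block_side)
  d <- dim(video$data)
  if (d[2] %% block_side != 0L || d[3] %% block_side != 0L) {
    stop("block side must divide the ROI sides", call. = FALSE)
  }
  if (block_side == 1L) return(video)
  h2 <- d[2] %/% block_side; w2 <- d[3] %/% block_side
  # group pixels (column-major within the H x W frame) by superpixel
  rows <- rep(seq_len(d[2]), times = d[3])
  cols <- rep(seq_len(d[3]), each = d[2])
  grp <- (ceiling(cols / block_side) - 1L) * h2 + ceiling(rows / block_side)
  m <- pixel_traces(video)
  sums <- rowsum(t(m), grp)                # K x T, groups in sorted order
  out <- t(sums) / block_side^2
  dim(out) <- c(d[1], h2, w2)
  v <- video
  v$data <- out
  v
}

#' Classify transition events into T1/T2/T3 by k-means
#'
#' Pools the detected events of a [detect_pixel_transitions()] run and
#' clusters them on standardized (time, half-width) features with k-means
#' (`stats::kmeans`, k-means++-style seeding via many restarts). Clusters
#' are relabeled T1, T2, ... by ascending mean time, so the labeling is
#' invariant to cluster-index permutations. With the default k = 3 the two
#' sub-transitions T2a/T2b fall into the single T2 cluster; k = 4 resolves
#' them.
#'
#' @param events Event `data.frame` (from `$events` of a detection run) or
#'   a `pixel_transition_set`.
#' @param k Number of transitions (default 3).
#' @param features Columns used for clustering; default `c("time",
#'   "half_width")`. `"time"` alone is also meaningful.
#' @param n_restarts k-means++ restarts; the best run by within-cluster
#'   sum of squares is kept.
#' @param seed Integer seed making the clustering deterministic.
#' @return Object of class `transition_catalog`: list with `events` (the
#'   input plus a `label` column), `summary` (per-label mean/sd time, mean
#'   half-width, pixel coverage fraction) and `k`.
#' @export
classify_transitions <- function(events, k = 3, features = c("time", "half_width"),
                                 n_restarts = 10, seed = 1L) {
  if (inherits(events, "pixel_transition_set")) {
    n_px <- events$height * events$width
    events <- events$events
  } else {
    n_px <- length(unique(events$pixel))
  }
  if (nrow(events) < k) stop("fewer events than clusters", call. = FALSE)
  x <- as.matrix(events[, features, drop = FALSE])
  mu <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  x <- sweep(sweep(x, 2L, mu, `-`), 2L, s, `/`)
  if (nrow(unique(x)) < k) stop("fewer than k distinct feature points", call. = FALSE)
  km <- with_seed(seed, kmeans_pp(x, k, n_restarts))
  # relabel by ascending mean time
  mean_t <- tapply(events$time, km$cluster, mean)
  ord <- order(mean_t)
  relab <- integer(k); relab[ord] <- seq_len(k)
  events$label <- paste0("T", relab[km$cluster])
  lev <- paste0("T", seq_len(k))
  summ <- do.call(rbind, lapply(lev, function(l) {
    e <- events[events$label == l, , drop = FALSE]
    data.frame(label = l,
               n = nrow(e),
               mean_time = mean(e$time),
               sd_time = stats::sd(e$time),
               mean_half_width = mean(e$half_width),
               coverage = length(unique(e$pixel)) / n_px)
  }))
  rownames(summ) <- NULL
  structure(list(events = events, summary = summ, k = k, n_pixels = n_px),
            class = "transition_catalog")
}

# k-means with k-means++ seeding: restarts draw distance-weighted initial
# centers, the best run by total within-cluster sum of squares wins.
kmeans_pp <- function(x, k, n_restarts) {
  n <- nrow(x)
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    ids <- integer(k)
    ids[1] <- sample.int(n, 1L)
    d2 <- rowSums((x - matrix(x[ids[1], ], n, ncol(x), byrow = TRUE))^2)
    for (j in seq_len(k - 1L) + 1L) {
      tot <- sum(d2)
      ids[j] <- if (tot > 0) {
        sample.int(n, 1L, prob = d2 / tot)
      } else {
        sample.int(n, 1L)
      }
      d2 <- pmin(d2, rowSums((x - matrix(x[ids[j], ], n, ncol(x), byrow = TRUE))^2))
    }
    centers <- x[ids, , drop = FALSE]
    if (anyDuplicated(centers)) centers <- centers +
        matrix(stats::rnorm(length(centers), 0, 1e-8), k)
    km <- tryCatch(stats::kmeans(x, centers = centers, iter.max = 100L),
                   error = function(e) NULL)
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss)) {
      best <- km
    }
  }
  if (is.null(best)) stop("k-means failed to converge", call. = FALSE)
  best
}

#' @export
print.transition_catalog <- function(x, ...) {
  cat(sprintf("<transition_catalog> %d events in %d clusters\n",
              nrow(x$events), x$k))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Synchrony profile across sampling areas
#'
#' Collects per-label transition statistics for catalogs computed at
#' several sampling-area sizes and summarizes scale invariance. For each
#' (area, label) pair the profile holds the mean and sd of the detected
#' transition times over superpixels; the scale-invariance metric for a
#' label is the maximum absolute difference between an area's mean time and
#' the reference (smallest-area) mean. The per-area sd column is the
#' synchrony diagnostic: under spatially synchronous transitions it shrinks
#' with block side as independent pixel jitter averages out, whereas a
#' deterministic spatial gradient keeps it from shrinking.
#'
#' @param catalogs Named list of [classify_transitions()] results, one per
#'   sampling area; names or `areas` give the block sides.
#' @param areas Integer block sides matching `catalogs`.
#' @return Object of class `synchrony_profile`: `profile` data frame (area,
#'   label, n, mean_time, sd_time, mean_half_width) and `invariance`
#'   (per-label max |mean - mean_ref| in s). Labels absent at an area are
#'   recorded as missing rows.
#' @export
synchrony_profile <- function(catalogs, areas = as.integer(names(catalogs))) {
  if (length(catalogs) < 2L) stop("need catalogs for at least two areas", call. = FALSE)
  if (length(areas) != length(catalogs) || anyNA(areas)) {
    stop("`areas` must give one block side per catalog", call. = FALSE)
  }
  labels <- sort(unique(unlist(lapply(catalogs, function(ct) ct$summary$label))))
  rows <- list()
  for (i in seq_along(catalogs)) {
    s <- catalogs[[i]]$summary
    for (l in labels) {
      r <- s[s$label == l, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        area = areas[i], label = l,
        n = if (nrow(r)) r$n else 0L,
        mean_time = if (nrow(r)) r$mean_time else NA_real_,
        sd_time = if (nrow(r)) r$sd_time else NA_real_,
        mean_half_width = if (nrow(r)) r$mean_half_width else NA_real_)
    }
  }
  prof <- do.call(rbind, rows)
  prof <- prof[order(prof$label, prof$area), ]
  rownames(prof) <- NULL
  ref_area <- min(areas)
  inv <- vapply(labels, function(l) {
    p <- prof[prof$label == l & !is.na(prof$mean_time), , drop = FALSE]
    ref <- p$mean_time[p$area == ref_area]
    if (!length(ref)) return(NA_real_)
    max(abs(p$mean_time - ref[1]))
  }, 0)
  structure(list(profile = prof, invariance = inv, reference_area = ref_area),
            class = "synchrony_profile")
}

#' @export
print.synchrony_profile <- function(x, ...) {
  cat("<synchrony_profile>\n")
  print(x$profile, row.names = FALSE)
  cat("max |mean - mean_ref| (s):\n")
  print(round(x$invariance, 3))
  invisible(x)
}

#' Bivariate histogram of transition time and half-width
#'
#' @param events Labeled or unlabeled event `data.frame` with `time` and
#'   `half_width` columns.
#' @param time_breaks,width_breaks Bin edges or bin counts (as in
#'   [graphics::hist()]); defaults choose ~50 x 30 bins over the data range.
#' @return Object of class `bivariate_histogram`: `counts` matrix (time
#'   bins x width bins), `time_edges`, `width_edges`. Counts sum to the
#'   number of events; an empty event set gives an all-zero histogram.
#' @export
bivariate_histogram <- function(events, time_breaks = 50, width_breaks = 30) {
  edges <- function(x, breaks) {
    if (length(breaks) > 1L) return(breaks)
    if (length(x) == 0L) return(seq(0, 1, length.out = breaks + 1L))
    r <- range(x)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = breaks + 1L)
  }
  te <- edges(events$time, time_breaks)
  we <- edges(events$half_width, width_breaks)
  counts <- matrix(0L, length(te) - 1L, length(we) - 1L)
  if (nrow(events)) {
    ti <- cut(events$time, te, include.lowest = TRUE, labels = FALSE)
    wi <- cut(events$half_width, we, include.lowest = TRUE, labels = FALSE)
    ok <- !is.na(ti) & !is.na(wi)
    for (i in which(ok)) counts[ti[i], wi[i]] <- counts[ti[i], wi[i]] + 1L
  }
  structure(list(counts = counts, time_edges = te, width_edges = we,
                 n_events = sum(counts)),
            class = "bivariate_histogram")
}

#' Fraction of pixels transitioning inside a time window
#'
#' For one transition label, computes the fraction of labeled pixels whose
#' event time lies within a window of `window_seconds` centered on the
#' label's modal time (mode of a histogram with `frame_interval`-wide
#' bins). Pixels with several events of the label contribute their
#' earliest. A designed T1 jitter of sd 1.5 s gives
#' erf(2.5 / (1.5 sqrt(2))) = 0.904 for a 5-s window.
#'
#' @param events Labeled event `data.frame` (needs `pixel`, `time`,
#'   `label`).
#' @param label Transition label, e.g. `"T1"`.
#' @param window_seconds Full window width (s).
#' @param frame_interval Bin width for the modal-time histogram (s).
#' @return List with `fraction`, `modal_time`, `n_pixels`.
#' @export
synchrony_fraction <- function(events, label, window_seconds,
                               frame_interval = 15.2 / 39) {
  e <- events[events$label == label, , drop = FALSE]
  if (nrow(e) == 0L) stop("label not present in events", call. = FALSE)
  t_px <- tapply(e$time, e$pixel, min)
  # bins aligned so that a bin center sits on the earliest time; keeps the
  # modal time exact for degenerate (zero-jitter) inputs
  br <- seq(min(t_px) - frame_interval / 2,
            max(t_px) + frame_interval, by = frame_interval)
  h <- graphics::hist(t_px, breaks = br, plot = FALSE)
  modal <- h$mids[which.max(h$counts)]
  frac <- mean(abs(t_px - modal) <= window_seconds / 2)
  list(fraction = frac, modal_time = unname(modal), n_pixels = length(t_px))
}
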