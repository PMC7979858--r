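test_that("superpixel schemes reproduce the sampling-area table", {
  sch <- superpixel_scheme(180)
  expect_equal(sch$sampling_areas, c(1L, 3L, 6L, 9L, 15L, 30L, 45L, 90L))
  expect_equal(sch$superpixels_per_side, c(180L, 60L, 30L, 20L, 12L, 6L, 4L, 2L))
  expect_error(superpixel_scheme(180, c(1, 7)), "divide")
})

test_that("superpixel resampling equals brute-force block means", {
  set.seed(4)
  arr <- array(runif(5 * 12 * 12) * 100, c(5, 12, 12))
  v <- intensity_video(arr, frame_interval = DT)
  expect_identical(resample_superpixels(v, 1), v)
  for (b in c(3L, 4L, 6L)) {
    r <- resample_superpixels(v, b)
    n2 <- 12L %/% b
    expect_equal(dim(r$data), c(5L, n2, n2))
    for (t in 1:5) for (i in seq_len(n2)) for (j in seq_len(n2)) {
      blk <- arr[t, ((i - 1) * b + 1):(i * b), ((j - 1) * b + 1):(j * b)]
      expect_lt(abs(r$data[t, i, j] - mean(blk)), 1e-9)
    }
  }
  expect_error(resample_superpixels(v, 5), "divide")
  # conservation: superpixel grand mean equals pixel grand mean
  r <- resample_superpixels(v, 6)
  expect_equal(mean(r$data), mean(arr), tolerance = 1e-12)
})

test_that("k-means classification recovers well-separated transitions", {
  # three point masses: perfect partition with zero within-cluster variance
  ev <- data.frame(pixel = 1:30,
                   time = rep(c(100, 250, 400), each = 10),
                   half_width = rep(c(2, 5, 8), each = 10))
  ct <- classify_transitions(ev, k = 3, seed = 1)
  expect_equal(ct$summary$mean_time, c(100, 250, 400))
  expect_equal(ct$summary$sd_time, c(0, 0, 0))
  expect_true(all(ct$events$label[ev$time == 100] == "T1"))
  expect_true(all(ct$events$label[ev$time == 400] == "T3"))
})

test_that("k-means partition matches the brute-force optimum on a small instance", {
  set.seed(5)
  n <- 20
  times <- c(rnorm(n, 100, 3), rnorm(n, 250, 3), rnorm(n, 400, 3))
  ev <- data.frame(pixel = seq_along(times), time = times,
                   half_width = rnorm(3 * n, 5, 0.1))
  ct <- classify_transitions(ev, k = 3, features = "time", seed = 2)
  # brute force: for 1D k-means the optimal partition is contiguous in
  # sorted order; enumerate all split points and minimize WCSS
  ts <- sort(times)
  z <- scale(times)[order(times)]
  best <- NULL; best_w <- Inf
  for (i in 1:(length(z) - 2)) for (j in (i + 1):(length(z) - 1)) {
    gr <- c(rep(1, i), rep(2, j - i), rep(3, length(z) - j))
    w <- sum(tapply(z, gr, function(v) sum((v - mean(v))^2)))
    if (w < best_w) { best_w <- w; best <- c(i, j) }
  }
  sizes <- as.integer(table(ct$events$label))
  expect_equal(sizes, c(best[1], best[2] - best[1], length(z) - best[2]))
  # deterministic for a fixed seed
  ct2 <- classify_transitions(ev, k = 3, features = "time", seed = 2)
  expect_identical(ct$events$label, ct2$events$label)
  expect_error(classify_transitions(ev[1:2, ], k = 3), "fewer")
})

test_that("detected T1 cluster matches the generator's design", {
  g <- small_video()
  det <- detect_pixel_transitions(g$video)
  ct <- classify_transitions(det, k = 3, seed = 1)
  s1 <- ct$summary[ct$summary$label == "T1", ]
  expect_equal(s1$mean_time, 227, tolerance = 1)
  expect_equal(s1$sd_time, 1.5, tolerance = 0.35)
  expect_equal(s1$coverage, 1)
  expect_true(all(diff(ct$summary$mean_time) > 0))
})

test_that("synchrony profile is exactly scale-invariant for synchronous noise-free input", {
  tp <- trace_params(noise_sd = 0)
  vp <- video_params(trace_params = tp, height = 12, width = 12,
                     n_frames = 1550, jitter_sd = 0, seed = 1)
  g <- generate_video(vp)
  cats <- list()
  for (b in c(1L, 3L, 6L)) {
    sv <- resample_superpixels(g$video, b)
    det <- detect_pixel_transitions(sv)
    cats[[as.character(b)]] <- classify_transitions(det, k = 3, seed = 1)
  }
  prof <- synchrony_profile(cats)
  expect_true(all(prof$invariance < 1e-9))
  expect_error(synchrony_profile(cats[1]), "two areas")
})

test_that("bivariate histogram conserves events and matches brute-force tallies", {
  ev1 <- data.frame(time = 100, half_width = 5)
  h1 <- bivariate_histogram(ev1)
  expect_equal(sum(h1$counts), 1L)
  expect_equal(max(h1$counts), 1L)

  set.seed(6)
  ev <- data.frame(time = runif(500, 0, 600), half_width = runif(500, 0, 20))
  te <- seq(0, 600, by = 50); we <- seq(0, 20, by = 2)
  h <- bivariate_histogram(ev, te, we)
  expect_equal(sum(h$counts), 500L)
  brute <- matrix(0L, length(te) - 1, length(we) - 1)
  for (r in seq_len(nrow(ev))) {
    i <- findInterval(ev$time[r], te, rightmost.closed = TRUE)
    j <- findInterval(ev$half_width[r], we, rightmost.closed = TRUE)
    brute[i, j] <- brute[i, j] + 1L
  }
  expect_equal(h$counts, brute)
  # empty input: an all-zero histogram, not an error
  h0 <- bivariate_histogram(ev[0, ])
  expect_equal(sum(h0$counts), 0L)
})

test_that("synchrony fraction behaves as a Gaussian-window coverage", {
  # zero jitter: everything inside any window wider than one frame
  ev <- data.frame(pixel = 1:50, time = rep(227, 50), label = "T1")
  expect_equal(synchrony_fraction(ev, "T1", DT)$fraction, 1)
  # designed jitter: ~erf(2.5 / (1.5 sqrt 2)) = 0.904 of pixels in 5 s
  g <- fixture("truth6060", function() {
    generate_video(video_params(height = 60, width = 60, n_frames = 1400,
                                seed = 8))
  })
  t1 <- g$truth[g$truth$label == "T1", ]
  ev <- data.frame(pixel = t1$pixel, time = t1$true_time, label = "T1")
  sf <- synchrony_fraction(ev, "T1", 5)
  expect_equal(sf$fraction, 0.9044, tolerance = 0.02)
  expect_equal(sf$modal_time, 227, tolerance = 0.6)
  # monotone in the window and saturating at 1
  f2 <- synchrony_fraction(ev, "T1", 2)$fraction
  f8 <- synchrony_fraction(ev, "T1", 8)$fraction
  expect_true(f2 <= sf$fraction && sf$fraction <= f8)
  expect_equal(synchrony_fraction(ev, "T1", 1e6)$fraction, 1)
  expect_error(synchrony_fraction(ev, "T9", 5), "not present")
})
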