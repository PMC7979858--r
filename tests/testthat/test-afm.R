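test_that("line-by-line flattening removes tilt exactly and is idempotent", {
  tilt <- outer(0.01 * (1:64), rep(1, 64)) + outer(rep(1, 64), 0.02 * (1:64))
  t0 <- topograph(tilt, nm_per_px = 0.39)
  f <- flatten_lines(t0)
  expect_lt(max(abs(f$heights)), 1e-9)

  g <- generate_topograph(lattice_presets("AUC", tilt_plane = c(0.02, 0.015)))
  f1 <- flatten_lines(g$topograph)
  # brute-force per-row regression oracle
  z <- g$topograph$heights
  brute <- t(apply(z, 1, function(row) stats::residuals(stats::lm(row ~ seq_along(row)))))
  expect_lt(max(abs(f1$heights - brute)), 1e-9)
  f2 <- flatten_lines(f1)
  expect_lt(max(abs(f2$heights - f1$heights)), 1e-9)
})

test_that("autocorrelation equals brute-force circular shift-multiply-sum", {
  set.seed(7)
  z <- matrix(rnorm(16 * 16), 16, 16)
  a <- autocorrelate(topograph(z, nm_per_px = 1))
  expect_lt(max(abs(a$acf - center_acf(brute_acf(z)))), 1e-9)
  # centro-symmetry and unit origin
  expect_equal(a$acf[9, 9], 1)
  # reflect through the center: ACF(v) = ACF(-v)
  expect_lt(max(abs(a$acf[2:16, 2:16] - a$acf[16:2, 16:2])), 1e-9)
})

test_that("autocorrelation of noise is flat and of a grating is periodic", {
  set.seed(8)
  n <- 64
  a <- autocorrelate(topograph(matrix(rnorm(n * n), n, n), nm_per_px = 1))
  off <- a$acf
  off[33, 33] <- 0
  expect_lt(max(abs(off)), 5 / n)
  # cosine grating of period 10 px: first off-origin maximum at lag 10
  z <- matrix(cos(2 * pi * (1:60) / 10), 60, 60)
  ag <- autocorrelate(topograph(z, nm_per_px = 1))
  row0 <- ag$acf[, 31]
  lags <- (1:60) - 31
  peaks <- which(diff(sign(diff(row0))) == -2) + 1
  pos <- lags[peaks]
  expect_equal(min(abs(pos[pos != 0])), 10)
  expect_error(autocorrelate(topograph(matrix(1, 8, 8), nm_per_px = 1)),
               "constant")
})

test_that("denoising preserves a clean lattice and suppresses noise", {
  # a commensurate lattice (8-px cell on a 64-px frame) is circularly
  # periodic and its soft motif carries no power near Nyquist, so a
  # generous low-pass leaves it untouched
  soft <- list(list(pos = c(0.5, 0.5), sigma = 2.5, height = 1))
  clean_soft <- generate_topograph(lattice_params(
    a_length = 8, c_length = 8, cell_angle = 90, nm_per_px = 1,
    image_size = 64, motif = soft))$topograph
  d0 <- denoise(clean_soft, "fft_lowpass", cutoff_frac = 0.9)
  expect_lt(max(abs(d0$heights - clean_soft$heights)), 1e-6)
  clean <- generate_topograph(lattice_presets("AUC"))$topograph
  noisy <- generate_topograph(lattice_presets("AUC", roughness_sd = 0.15,
                                              seed = 9))$topograph
  dn <- denoise(noisy, "fft_lowpass", cutoff_frac = 0.35)
  expect_lt(sqrt(mean((dn$heights - clean$heights)^2)),
            sqrt(mean((noisy$heights - clean$heights)^2)))
  dc <- denoise(noisy, "correlation_average", patch_px = 40)
  expect_lt(sqrt(mean((dc$heights - clean$heights)^2)),
            sqrt(mean((noisy$heights - clean$heights)^2)))
  expect_error(denoise(clean, "fft_lowpass", cutoff_frac = 2), "Nyquist")
})

test_that("correlation averaging of identical patches returns the patch", {
  patch <- matrix(rnorm(16 * 16, sd = 0.5), 16, 16)
  tiled <- patch[rep(1:16, 4), rep(1:16, 4)]       # 64 x 64 perfect tiling
  t0 <- topograph(tiled, nm_per_px = 1)
  out <- denoise(t0, "correlation_average", patch_px = 16)
  expect_lt(max(abs(out$heights - tiled)), 1e-9)
})

test_that("unit-cell measurement recovers designed lattices", {
  sq <- generate_topograph(lattice_params(a_length = 10, c_length = 10,
                                          cell_angle = 90, nm_per_px = 1,
                                          image_size = 64))
  m <- measure_unit_cell(autocorrelate(sq$topograph), 5, 20)
  expect_true(m$ok)
  expect_equal(m$a_len, 10, tolerance = 0.05)
  expect_equal(m$c_len, 10, tolerance = 0.05)
  expect_equal(m$angle, 90, tolerance = 2)

  # oblique lattice with noise at 10% of the corrugation amplitude
  npp <- 100 / 256
  ob <- generate_topograph(lattice_params(a_length = 12.3 * npp,
                                          c_length = 23.8 * npp,
                                          cell_angle = 90, nm_per_px = npp,
                                          image_size = 256,
                                          roughness_sd = 0.1, seed = 3))
  mo <- measure_unit_cell(autocorrelate(flatten_lines(ob$topograph)), 2, 20)
  expect_true(mo$ok)
  expect_lt(abs(mo$a_len - 12.3 * npp), 0.5 * npp)
  expect_lt(abs(mo$c_len - 23.8 * npp), 0.5 * npp)
})

test_that("the designed c-axis spacing dominates the autocorrelation rows", {
  # c = 9.3 nm at 0.390625 nm/px is 23.8 px between ACF peak rows
  g <- generate_topograph(lattice_presets("AUC"))
  a <- autocorrelate(g$topograph)
  m <- measure_unit_cell(a, 2, 20)
  cpx <- m$c_len / a$nm_per_px
  expect_equal(cpx, 9.3 / (100 / 256), tolerance = 0.05)
})

test_that("measurement is invariant to height scaling and transposition", {
  g <- generate_topograph(lattice_presets("TUC1", roughness_sd = 0.05, seed = 5))
  a1 <- autocorrelate(g$topograph)
  m1 <- measure_unit_cell(a1, 2, 20)
  t2 <- g$topograph
  t2$heights <- 7.5 * t2$heights
  m2 <- measure_unit_cell(autocorrelate(t2), 2, 20)
  expect_equal(m1$a_len, m2$a_len, tolerance = 1e-9)
  expect_equal(m1$c_len, m2$c_len, tolerance = 1e-9)
  t3 <- g$topograph
  t3$heights <- t(t3$heights)
  m3 <- measure_unit_cell(autocorrelate(t3), 2, 20)
  expect_equal(sort(c(m3$a_len, m3$c_len)), sort(c(m1$a_len, m1$c_len)),
               tolerance = 0.05)
})

test_that("noise-free spacing recovery stays within half a pixel across spacings", {
  for (s in c(6, 10, 16, 24, 34)) {
    g <- generate_topograph(lattice_params(a_length = s, c_length = s,
                                           cell_angle = 90, nm_per_px = 1,
                                           image_size = max(64, 5 * s),
                                           motif = list(list(pos = c(0.5, 0.5),
                                                             sigma = max(1, s / 8),
                                                             height = 1))))
    m <- measure_unit_cell(autocorrelate(g$topograph), s / 2, 1.5 * s)
    expect_true(m$ok)
    expect_lt(abs(m$a_len - s), 0.5)
    expect_lt(abs(m$c_len - s), 0.5)
  }
})

test_that("a homogeneous image measured in two halves gives one cell", {
  g <- generate_topograph(lattice_presets("AUC", image_size = c(256, 256),
                                          roughness_sd = 0.05, seed = 6))
  regs <- list(list(rows = c(1, 256), cols = c(1, 128)),
               list(rows = c(1, 256), cols = c(129, 256)))
  ms <- measure_regions(g$topograph, regs)
  expect_true(ms[[1]]$ok && ms[[2]]$ok)
  expect_equal(ms[[1]]$c_len, ms[[2]]$c_len, tolerance = 0.15)
  # a 4 x 4 px region fails gracefully while others proceed
  ms2 <- measure_regions(g$topograph, c(regs, list(list(rows = c(1, 4), cols = c(1, 4)))))
  expect_true(ms2[[1]]$ok)
  expect_false(ms2[[3]]$ok)
})

test_that("a three-region mixed topograph reproduces its per-region cells", {
  regs <- list(
    region_spec(c(1, 256), c(1, 128), lattice_presets("TUC1")),
    region_spec(c(1, 256), c(129, 256), lattice_presets("intermediate")),
    region_spec(c(1, 256), c(257, 384), lattice_presets("AUC")))
  mx <- generate_mixed_topograph(regs, image_size = c(256, 384),
                                 roughness_sd = 0.05, seed = 2)
  ms <- measure_regions(mx$topograph, regs)
  got <- vapply(ms, function(m) m$c_len, 0)
  expect_equal(got, c(7.9, 12.5, 9.3), tolerance = 0.3 / 7.9)
  # the TUC1 and intermediate regions differ by more than 3 nm
  expect_gt(abs(got[2] - got[1]), 3)
  # overlap rejection and single-region equivalence
  expect_error(generate_mixed_topograph(list(regs[[1]], regs[[1]])), "overlap")
  solo <- generate_mixed_topograph(
    list(region_spec(c(1, 128), c(1, 128), lattice_presets("AUC")),
         region_spec(c(129, 256), c(1, 128), lattice_presets("AUC"))),
    image_size = c(256, 128), roughness_sd = 0)
  direct <- generate_topograph(lattice_presets("AUC", image_size = c(256, 128)))
  expect_equal(solo$topograph$heights, direct$topograph$heights,
               tolerance = 1e-9)
})

test_that("c-axis series get phase labels from the nearest reference", {
  ts <- caxis_timeseries(data.frame(index = 1:4, c_len = c(9.3, 9.3, 7.9, 7.9)))
  expect_equal(ts$phase, c("AUC", "AUC", "TUC1", "TUC1"))
  expect_equal(caxis_timeseries(data.frame(index = 1, c_len = 12.4))$phase, "TUC2")
  expect_equal(caxis_timeseries(data.frame(index = 1, c_len = 10.8))$phase,
               "intermediate")
  expect_equal(caxis_timeseries(data.frame(index = 1, c_len = NA))$phase, "gap")
  ts0 <- caxis_timeseries(data.frame(index = 1:2, c_len = c(9.3, 7.9)),
                          references = numeric(0))
  expect_equal(ts0$phase, c("unassigned", "unassigned"))
})

test_that("mean height is tilt-independent after flattening within noise", {
  g1 <- generate_topograph(lattice_presets("AUC", roughness_sd = 0.05, seed = 12))
  g2 <- generate_topograph(lattice_presets("AUC", roughness_sd = 0.05,
                                           tilt_plane = c(0.03, 0.02), seed = 12))
  m1 <- mean(flatten_lines(g1$topograph)$heights)
  m2 <- mean(flatten_lines(g2$topograph)$heights)
  expect_lt(abs(m1 - m2), 0.05 / sqrt(length(g1$topograph$heights)) * 10)
})
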