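pvm_cfg <- function(dir, seed = 5) {
  list(synthetic = list(height = 12, width = 12, n_frames = 1550),
       sampling_areas = c(1, 3, 6), seed = seed, output_dir = dir)
}

test_that("the PVM pipeline produces three labeled transitions and its manifest", {
  dir <- withr::local_tempdir()
  s <- suppressMessages(run_pvm_pipeline(pvm_cfg(dir)))
  expect_equal(sort(s$transitions$label), c("T1", "T2", "T3"))
  expect_equal(s$n_pixels, 144L)
  expect_equal(s$transitions$mean_time[s$transitions$label == "T1"], 227,
               tolerance = 1)
  expect_equal(s$mean_trace_fractional_loss, 0.5, tolerance = 0.02)
  for (f in unlist(s$outputs)) expect_true(file.exists(file.path(dir, f)))
  # every declared output exists and the summary parses back
  js <- jsonlite::fromJSON(file.path(dir, "pvm_summary.json"))
  expect_equal(js$seed, 5)
})

test_that("reruns with the same config and seed are byte-identical", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressMessages(run_pvm_pipeline(pvm_cfg(d1)))
  suppressMessages(run_pvm_pipeline(pvm_cfg(d2)))
  for (f in c("pvm_events.csv", "pvm_synchrony.csv", "pvm_histogram.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     info = f)
  }
})

test_that("configs must name exactly one input source", {
  expect_error(suppressMessages(run_pvm_pipeline(list(output_dir = tempdir()))),
               "exactly one")
  expect_error(suppressMessages(run_pvm_pipeline(
    list(synthetic = list(), input = list(path = "x"), output_dir = tempdir()))),
    "exactly one")
  expect_error(suppressMessages(run_afm_pipeline(list(output_dir = tempdir()))),
               "exactly one")
})

test_that("config files round-trip through YAML and JSON", {
  cfg <- list(seed = 3, synthetic = list(height = 12, width = 12))
  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, fy)
  expect_equal(read_run_config(fy)$synthetic$height, 12)
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, fj, auto_unbox = TRUE)
  expect_equal(read_run_config(fj)$seed, 3)
  expect_error(read_run_config("no/such/file.yaml"), "not found")
})

test_that("the AFM pipeline tracks a phase change and flags gaps", {
  dir <- withr::local_tempdir()
  cfg <- list(
    synthetic = list(
      roughness_sd = 0.05,
      series = list(list(phase = "AUC"), list(phase = "AUC"),
                    list(gap = TRUE),
                    list(phase = "TUC1"), list(phase = "TUC1"))),
    seed = 4, output_dir = dir)
  r <- suppressMessages(run_afm_pipeline(cfg))
  ts <- r$timeseries
  expect_equal(ts$phase, c("AUC", "AUC", "gap", "TUC1", "TUC1"))
  # exactly one phase change among measured frames
  ph <- ts$phase[ts$phase != "gap"]
  expect_equal(sum(ph[-1] != ph[-length(ph)]), 1L)
  expect_true(file.exists(file.path(dir, "afm_cells.csv")))
  expect_true(file.exists(file.path(dir, "afm_caxis_timeseries.csv")))
})

test_that("a mixed image contributes one row per region", {
  dir <- withr::local_tempdir()
  cfg <- list(
    synthetic = list(
      roughness_sd = 0.05,
      series = list(
        list(phase = "TUC1"),
        list(regions = list(
          list(phase = "TUC1", rows = c(1, 256), cols = c(1, 128)),
          list(phase = "intermediate", rows = c(1, 256), cols = c(129, 256)),
          list(phase = "AUC", rows = c(1, 256), cols = c(257, 384)))))),
    seed = 4, output_dir = dir)
  r <- suppressMessages(run_afm_pipeline(cfg))
  expect_equal(sum(r$measurements$index == 2), 3L)
  expect_equal(r$measurements$c_len[r$measurements$index == 2],
               c(7.9, 12.5, 9.3), tolerance = 0.05)
})

test_that("an empty AFM series yields an empty table with headers", {
  dir <- withr::local_tempdir()
  r <- suppressMessages(run_afm_pipeline(list(synthetic = list(series = list()),
                                              output_dir = dir)))
  expect_equal(nrow(r$measurements), 0L)
  got <- utils::read.csv(file.path(dir, "afm_cells.csv"))
  expect_true(all(c("index", "c_len", "ok") %in% names(got)))
})

test_that("AFM images load from TIFF and plain-text matrices", {
  dir <- withr::local_tempdir()
  g <- generate_topograph(lattice_presets("TUC1", roughness_sd = 0.05, seed = 3))
  ft <- file.path(dir, "img1.txt")
  write.table(g$topograph$heights, ft, row.names = FALSE, col.names = FALSE)
  cfg <- list(input = list(images = list(ft, "missing.txt"),
                           nm_per_px = 100 / 256),
              seed = 1, output_dir = dir)
  r <- suppressMessages(run_afm_pipeline(cfg))
  expect_equal(nrow(r$measurements), 2L)
  expect_equal(r$measurements$c_len[1], 7.9, tolerance = 0.1)
  expect_false(r$measurements$ok[2])   # unreadable image flagged, run continues
})
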