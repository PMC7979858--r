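#' Read a pipeline run configuration
#'
#' Loads a YAML (`.yml`/`.yaml`) or JSON configuration file into the
#' nested list consumed by [run_pvm_pipeline()] and [run_afm_pipeline()].
#'
#' @param path Configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the PVM transition-kinetics pipeline
#'
#' End-to-end analysis of a polarized-video-microscopy run: obtain the ROI
#' video (either loaded from disk or generated by the synthetic module),
#' detect per-pixel transition events, classify them into transitions by
#' k-means, resample at every sampling-area size, and write the event
#' catalog, synchrony profile, bivariate histogram, plots and a JSON
#' summary to the output directory. Deterministic for a fixed config seed.
#'
#' @param config Nested list (or path to a YAML/JSON file). Recognized
#'   elements: exactly one of `synthetic` (fields of [video_params()]) or
#'   `input` (`path`, `frame_interval`, `pixel_size`, `start_frame`,
#'   optional `roi` with `top`/`left`/`side`); optional `trace_smooth_seconds`
#'   (15.2), `derivative_smooth_seconds` (7.78), `peak_find` (fields of
#'   [peak_find_params()]), `k` (3), `sampling_areas` (1,3,6,9,15,30,45,90
#'   where they divide the ROI), `synchrony_window_seconds` (5), `seed`,
#'   `output_dir`.
#' @param output_dir Overrides `config$output_dir`.
#' @return Invisibly, the summary list (also written as `pvm_summary.json`).
#' @export
run_pvm_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- output_dir %||% config$output_dir %||% stop("no output_dir", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)

  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$input)
  if (has_syn == has_inp) {
    stop("config must have exactly one of `synthetic` or `input`", call. = FALSE)
  }
  truth <- NULL
  if (has_syn) {
    vp <- do.call(video_params, utils::modifyList(config$synthetic,
                                                  list(seed = seed)))
    log_stage("simulate", "generating %d x %d x %d synthetic video",
              vp$n_frames, vp$height, vp$width)
    g <- generate_video(vp)
    video <- g$video
    truth <- g$truth
  } else {
    inp <- config$input
    log_stage("load", "reading %s", inp$path)
    video <- load_video_frames(inp$path, frame_interval = inp$frame_interval,
                               pixel_size = inp$pixel_size %||% 24.75,
                               start_frame = inp$start_frame %||% 1L)
    if (!is.null(inp$roi)) {
      video <- extract_roi(video, roi_spec(inp$roi$top %||% 1L,
                                           inp$roi$left %||% 1L, inp$roi$side))
    }
  }

  pf <- do.call(peak_find_params, config$peak_find %||% list())
  tsm <- config$trace_smooth_seconds %||% 15.2
  dsm <- config$derivative_smooth_seconds %||% 7.78
  k <- config$k %||% 3
  side <- dim(video$data)[2]
  areas <- as.integer(config$sampling_areas %||% c(1, 3, 6, 9, 15, 30, 45, 90))
  areas <- areas[side %% areas == 0 & dim(video$data)[3] %% areas == 0]
  win <- config$synchrony_window_seconds %||% 5

  log_stage("detect", "per-pixel detection on %d traces", prod(dim(video$data)[2:3]))
  det <- detect_pixel_transitions(video, tsm, dsm, pf)
  log_stage("detect", "%d events; %d/%d pixels without detection",
            nrow(det$events), sum(det$n_events == 0L), length(det$n_events))
  cat1 <- classify_transitions(det, k = k, seed = seed)

  catalogs <- list()
  for (b in areas) {
    if (b == 1L) {
      catalogs[[as.character(b)]] <- cat1
      next
    }
    sv <- resample_superpixels(video, b)
    db <- detect_pixel_transitions(sv, tsm, dsm, pf)
    catalogs[[as.character(b)]] <- classify_transitions(db, k = k, seed = seed)
    log_stage("superpixel", "block %d: %d events over %d superpixels",
              b, nrow(db$events), length(db$n_events))
  }
  prof <- synchrony_profile(catalogs, areas)
  hist2 <- bivariate_histogram(cat1$events)
  fracs <- lapply(unique(cat1$events$label), function(l) {
    sf <- synchrony_fraction(cat1$events, l, win, video$frame_interval)
    c(label = l, fraction = sf$fraction, modal_time = sf$modal_time)
  })
  fracs <- as.data.frame(do.call(rbind, fracs))
  loss <- trace_summary(rowMeans(pixel_traces(video)))

  files <- list(events = "pvm_events.csv", synchrony = "pvm_synchrony.csv",
                histogram = "pvm_histogram.csv", summary = "pvm_summary.json",
                plot_profile = "pvm_synchrony.png",
                plot_histogram = "pvm_histogram.png")
  ev <- cat1$events[, c("pixel", "label", "time", "half_width", "amplitude")]
  names(ev) <- c("pixel", "label", "time_s", "half_width_s", "amplitude")
  utils::write.csv(ev, file.path(out_dir, files$events), row.names = FALSE)
  utils::write.csv(prof$profile, file.path(out_dir, files$synchrony),
                   row.names = FALSE)
  hm <- as.data.frame(as.table(hist2$counts))
  names(hm) <- c("time_bin", "width_bin", "count")
  utils::write.csv(hm, file.path(out_dir, files$histogram), row.names = FALSE)

  grDevices::png(file.path(out_dir, files$plot_profile), 800, 600)
  plot_synchrony_profile(prof)
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, files$plot_histogram), 800, 600)
  plot_bivariate_histogram(hist2)
  grDevices::dev.off()

  summary <- list(
    seed = seed,
    n_pixels = length(det$n_events),
    n_events = nrow(det$events),
    modal_events_per_pixel = as.integer(names(sort(table(det$n_events),
                                                   decreasing = TRUE))[1]),
    transitions = cat1$summary,
    synchrony_fractions = fracs,
    scale_invariance_s = as.list(prof$invariance),
    mean_trace_fractional_loss = loss$fractional_loss,
    sampling_areas = areas,
    outputs = files
  )
  jsonlite::write_json(summary, file.path(out_dir, files$summary),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("report", "summary written to %s", file.path(out_dir, files$summary))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

plot_synchrony_profile <- function(prof) {
  p <- prof$profile[!is.na(prof$profile$mean_time), ]
  labs <- unique(p$label)
  cols <- grDevices::hcl.colors(max(3, length(labs)), "Dark 3")
  graphics::plot(NA, xlim = range(p$area), ylim = range(p$mean_time) + c(-5, 5),
                 log = "x", xlab = "sampling area side (px)",
                 ylab = "transition time (s)",
                 main = "Transition time vs sampling area")
  for (i in seq_along(labs)) {
    q <- p[p$label == labs[i], ]
    graphics::points(q$area, q$mean_time, col = cols[i], pch = 19, type = "b")
    has_bar <- !is.na(q$sd_time) & q$sd_time > 0
    if (any(has_bar)) {
      graphics::arrows(q$area[has_bar], (q$mean_time - q$sd_time)[has_bar],
                       q$area[has_bar], (q$mean_time + q$sd_time)[has_bar],
                       angle = 90, code = 3, length = 0.03, col = cols[i])
    }
  }
  graphics::legend("topleft", legend = labs, col = cols[seq_along(labs)], pch = 19)
}

plot_bivariate_histogram <- function(h) {
  graphics::image(x = h$time_edges, y = h$width_edges,
                  z = log1p(h$counts), col = grDevices::hcl.colors(64, "Inferno"),
                  xlab = "transition time (s)", ylab = "half-width (s)",
                  main = "Bivariate histogram (log counts)")
}

#' Run the AFM lattice-measurement pipeline
#'
#' Measures the surface unit cell for a series of AFM topographs (loaded
#' or synthetic), assembles the phase-labeled c-axis time series, and
#' writes per-image/per-region measurements, the time series and a plot.
#' Unreadable or unmeasurable images are flagged as gaps and the run
#' continues.
#'
#' @param config Nested list (or YAML/JSON path). Exactly one of
#'   `synthetic` (list `series`: per image a list with `phase` — a
#'   [lattice_presets()] name — or `lattice` overrides, or `regions` for a
#'   mixed image; plus optional shared `roughness_sd`, `tilt_plane`,
#'   `nm_per_px`, `image_size`) or `input` (list `images` of file paths:
#'   TIFF or whitespace-delimited height matrices in nm; `nm_per_px`).
#'   Optional: `flatten` (TRUE), `denoise` (`"none"`, `"fft_lowpass"`,
#'   `"correlation_average"`), `min_spacing_nm`, `max_spacing_nm`,
#'   `references` (named c-axis list), `max_dev_nm`, `frame_time_s`
#'   (acquisition time per image), `seed`, `output_dir`.
#' @param output_dir Overrides `config$output_dir`.
#' @return Invisibly, a list with `measurements` (data.frame) and
#'   `timeseries` (the [caxis_timeseries()] result).
#' @export
run_afm_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- output_dir %||% config$output_dir %||% stop("no output_dir", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$input)
  if (has_syn == has_inp) {
    stop("config must have exactly one of `synthetic` or `input`", call. = FALSE)
  }

  topos <- list()   # per image: list(topo = , regions = NULL or list)
  if (has_syn) {
    syn <- config$synthetic
    series <- syn$series %||% list()
    for (i in seq_along(series)) {
      s <- series[[i]]
      common <- list(roughness_sd = syn$roughness_sd %||% 0.05,
                     seed = seed + i)
      if (!is.null(syn$nm_per_px)) common$nm_per_px <- syn$nm_per_px
      if (!is.null(s$regions)) {
        regs <- lapply(s$regions, function(r) {
          lp <- do.call(lattice_presets,
                        utils::modifyList(list(phase = r$phase), r$lattice %||% list()))
          region_spec(r$rows, r$cols, lp)
        })
        g <- generate_mixed_topograph(regs,
                                      image_size = syn$mixed_image_size %||% c(256, 384),
                                      nm_per_px = syn$nm_per_px %||% (100 / 256),
                                      roughness_sd = common$roughness_sd,
                                      seed = seed + i)
        topos[[i]] <- list(topo = g$topograph, regions = regs)
      } else if (!is.null(s$gap) && isTRUE(s$gap)) {
        topos[[i]] <- list(topo = NULL, regions = NULL)
      } else {
        lp <- do.call(lattice_presets,
                      utils::modifyList(c(list(phase = s$phase), common),
                                        s$lattice %||% list()))
        g <- generate_topograph(lp)
        topos[[i]] <- list(topo = g$topograph, regions = NULL)
      }
    }
  } else {
    npp <- config$input$nm_per_px %||% (100 / 256)
    for (i in seq_along(config$input$images)) {
      f <- config$input$images[[i]]
      topos[[i]] <- tryCatch({
        z <- suppressWarnings(if (grepl("\\.tiff?$", f, ignore.case = TRUE)) {
          tiff::readTIFF(f)
        } else {
          as.matrix(utils::read.table(f))
        })
        dimnames(z) <- NULL
        list(topo = topograph(z, nm_per_px = npp), regions = NULL)
      }, error = function(e) {
        log_stage("load", "image %d unreadable (%s); flagged as gap", i,
                  conditionMessage(e))
        list(topo = NULL, regions = NULL)
      })
    }
  }

  do_flatten <- config$flatten %||% TRUE
  dn_mode <- config$denoise %||% "none"
  msp <- config$min_spacing_nm %||% 2
  xsp <- config$max_spacing_nm %||% 20
  frame_time <- config$frame_time_s %||% NA_real_

  rows <- list()
  for (i in seq_along(topos)) {
    tp <- topos[[i]]
    if (is.null(tp$topo)) {
      rows[[length(rows) + 1L]] <- data.frame(index = i, region = NA_integer_,
                                              a_len = NA_real_, c_len = NA_real_,
                                              angle = NA_real_, ok = FALSE)
      next
    }
    t1 <- tp$topo
    if (isTRUE(do_flatten)) t1 <- flatten_lines(t1)
    if (dn_mode != "none") t1 <- denoise(t1, dn_mode)
    if (!is.null(tp$regions)) {
      ms <- measure_regions(t1, tp$regions, min_spacing_nm = msp,
                            max_spacing_nm = xsp)
      for (j in seq_along(ms)) {
        m <- ms[[j]]
        rows[[length(rows) + 1L]] <- data.frame(index = i, region = j,
                                                a_len = m$a_len, c_len = m$c_len,
                                                angle = m$angle, ok = m$ok)
      }
    } else {
      m <- tryCatch(measure_unit_cell(autocorrelate(t1), msp, xsp),
                    error = function(e) {
                      log_stage("measure", "image %d failed: %s", i,
                                conditionMessage(e))
                      NULL
                    })
      rows[[length(rows) + 1L]] <- data.frame(
        index = i, region = NA_integer_,
        a_len = if (is.null(m)) NA_real_ else m$a_len,
        c_len = if (is.null(m)) NA_real_ else m$c_len,
        angle = if (is.null(m)) NA_real_ else m$angle,
        ok = !is.null(m) && m$ok)
    }
  }
  meas <- if (length(rows)) do.call(rbind, rows) else
    data.frame(index = integer(0), region = integer(0), a_len = numeric(0),
               c_len = numeric(0), angle = numeric(0), ok = logical(0))
  if (!is.na(frame_time)) meas$time_s <- (meas$index - 1) * frame_time

  # time series over whole-image measurements (first/only region per index)
  first <- meas[is.na(meas$region) | meas$region == 1L, , drop = FALSE]
  ts <- if (nrow(first)) {
    caxis_timeseries(data.frame(index = first$index, c_len = first$c_len),
                     references = unlist(config$references %||%
                                           list(AUC = 9.3, TUC1 = 7.9, TUC2 = 12.4)),
                     max_dev_nm = config$max_dev_nm %||% 1.0)
  } else {
    NULL
  }

  utils::write.csv(meas, file.path(out_dir, "afm_cells.csv"), row.names = FALSE)
  if (!is.null(ts)) {
    utils::write.csv(as.data.frame(ts), file.path(out_dir, "afm_caxis_timeseries.csv"),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, "afm_caxis.png"), 800, 600)
    plot_caxis_timeseries(ts)
    grDevices::dev.off()
  }
  log_stage("report", "%d measurements (%d gaps/failures) written to %s",
            nrow(meas), sum(!meas$ok), out_dir)
  invisible(list(measurements = meas, timeseries = ts))
}

plot_caxis_timeseries <- function(ts) {
  ok <- is.finite(ts$c_len)
  if (!any(ok)) return(invisible())
  graphics::plot(ts$index[ok], ts$c_len[ok], pch = 19,
                 xlab = "serial image number", ylab = "c-axis length (nm)",
                 main = "c-axis vs image number")
  graphics::text(ts$index[ok], ts$c_len[ok], labels = ts$phase[ok],
                 pos = 3, cex = 0.7)
}
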