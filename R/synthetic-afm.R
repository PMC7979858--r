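#' Parameters of a synthetic lattice topograph
#'
#' Describes an AFM-like height image of a 2D crystal surface: Gaussian
#' molecular motifs repeated on an oblique lattice with in-plane vectors of
#' lengths `a_length` and `c_length` (nm) separated by `cell_angle`
#' degrees, plus an instrumental tilt plane and Gaussian roughness. The
#' `a` vector lies along the image x (column) axis; `c` points into the
#' upper half-plane. The default calibration of 100/256 = 0.390625 nm/px
#' reproduces a 100-nm scan digitized at 256 pixels.
#'
#' All image coordinates in this package are 1-based (R convention), rows
#' increasing downward, pixels addressed column-major.
#'
#' @param a_length,c_length In-plane lattice constants (nm); both must
#'   exceed 2 pixels.
#' @param cell_angle Angle between the lattice vectors (deg, in (0, 180)).
#' @param motif List of motif blobs, each a list with `pos` (fractional
#'   coordinates in the cell), `sigma` (nm) and `height` (nm).
#' @param nm_per_px Calibration (nm per pixel).
#' @param image_size Image size in px; scalar or `c(rows, cols)`. The
#'   image must cover at least 4 cells per axis.
#' @param tilt_plane `c(slope_x, slope_y)` in nm/px.
#' @param roughness_sd Gaussian height noise sd (nm).
#' @param seed Integer seed for the roughness.
#' @return Object of class `lattice_params`.
#' @export
lattice_params <- function(a_length = 4.83, c_length = 9.3, cell_angle = 94.5,
                           motif = list(list(pos = c(0.5, 0.5), sigma = 0.8,
                                             height = 1.0)),
                           nm_per_px = 100 / 256,
                           image_size = 256,
                           tilt_plane = c(0, 0),
                           roughness_sd = 0,
                           seed = 1L) {
  stopifnot_scalar(a_length, "a_length", positive = TRUE)
  stopifnot_scalar(c_length, "c_length", positive = TRUE)
  stopifnot_scalar(nm_per_px, "nm_per_px", positive = TRUE)
  stopifnot_scalar(roughness_sd, "roughness_sd", nonneg = TRUE)
  if (cell_angle <= 0 || cell_angle >= 180) {
    stop("cell_angle must lie in (0, 180) degrees", call. = FALSE)
  }
  if (min(a_length, c_length) <= 2 * nm_per_px) {
    stop("lattice constants must exceed 2 pixels", call. = FALSE)
  }
  image_size <- rep_len(as.integer(image_size), 2L)
  span_nm <- image_size * nm_per_px            # rows, cols
  if (span_nm[2] < 4 * a_length || span_nm[1] < 4 * c_length * abs(sinpi(cell_angle / 180))) {
    stop("image must cover at least 4 cells per axis", call. = FALSE)
  }
  structure(
    list(a_length = a_length, c_length = c_length, cell_angle = cell_angle,
         motif = motif, nm_per_px = nm_per_px, image_size = image_size,
         tilt_plane = as.numeric(tilt_plane), roughness_sd = roughness_sd,
         seed = as.integer(seed)),
    class = "lattice_params"
  )
}

#' Lattice presets for the observed crystal phases
#'
#' In-plane (a, c, angle) constants of the surface lattices traversed
#' during the ligand-triggered transition: the apo cell AUC (a = 4.83 nm,
#' c = 9.3 nm, 94.5 deg), the first transition cell TUC1 (a = 5.03 nm,
#' c = 7.9 nm, 90.6 deg), the second transition cell TUC2 (c = 12.4 nm)
#' and the mixed-image intermediate region (c = 12.5 nm). The a-axis and
#' angle of TUC2 and of the intermediate are not independently measured;
#' the TUC1 values are reused for them.
#'
#' @param phase One of `"AUC"`, `"TUC1"`, `"TUC2"`, `"intermediate"`.
#' @param ... Overrides passed to [lattice_params()].
#' @return A [lattice_params()] object.
#' @export
lattice_presets <- function(phase = c("AUC", "TUC1", "TUC2", "intermediate"),
                            ...) {
  phase <- match.arg(phase)
  base <- switch(phase,
    AUC = list(a_length = 4.83, c_length = 9.3, cell_angle = 94.5),
    TUC1 = list(a_length = 5.03, c_length = 7.9, cell_angle = 90.6),
    TUC2 = list(a_length = 5.03, c_length = 12.4, cell_angle = 90.6),
    intermediate = list(a_length = 5.03, c_length = 12.5, cell_angle = 90.6))
  do.call(lattice_params, utils::modifyList(base, list(...)))
}

# Render the noiseless, untilted lattice height field for params `p`
# over an image of size `image_size` (rows, cols).
render_lattice_field <- function(p, image_size = p$image_size) {
  h <- image_size[1]; w <- image_size[2]
  npp <- p$nm_per_px
  ang <- p$cell_angle * pi / 180
  va <- c(p$a_length, 0)                          # (x, y) nm
  vc <- c(p$c_length * cos(ang), p$c_length * sin(ang))
  span_x <- w * npp; span_y <- h * npp
  margin <- 4 * max(vapply(p$motif, function(m) m$sigma, 0)) +
    max(p$a_length, p$c_length)
  z <- matrix(0, h, w)
  n_range <- floor(-margin / vc[2]):ceiling((span_y + margin) / vc[2])
  for (n in n_range) {
    x_off <- n * vc[1]
    m_range <- floor((-margin - x_off) / va[1]):ceiling((span_x + margin - x_off) / va[1])
    for (m in m_range) {
      origin <- m * va + n * vc
      for (mo in p$motif) {
        ctr <- origin + mo$pos[1] * va + mo$pos[2] * vc
        # pixel window of +/- 4 sigma around the blob center
        cx <- ctr[1] / npp + 1; cy <- ctr[2] / npp + 1
        rad <- 6 * mo$sigma / npp
        x_lo <- max(1L, floor(cx - rad)); x_hi <- min(w, ceiling(cx + rad))
        y_lo <- max(1L, floor(cy - rad)); y_hi <- min(h, ceiling(cy + rad))
        if (x_lo > x_hi || y_lo > y_hi) next
        xs <- x_lo:x_hi
        ys <- y_lo:y_hi
        dx <- (xs - cx) * npp
        dy <- (ys - cy) * npp
        z[ys, xs] <- z[ys, xs] +
          mo$height * exp(-outer(dy^2, dx^2, `+`) / (2 * mo$sigma^2))
      }
    }
  }
  z
}

#' Generate a synthetic AFM topograph with known unit cell
#'
#' Renders Gaussian motifs on the designed oblique lattice, adds the tilt
#' plane and Gaussian roughness, and returns the designed cell alongside.
#'
#' @param params A [lattice_params()] object.
#' @return List with `topograph` (a [topograph()]) and `truth` (a list with
#'   `a_length`, `c_length`, `cell_angle`).
#' @export
generate_topograph <- function(params) {
  if (!inherits(params, "lattice_params")) params <- do.call(lattice_params, params)
  p <- params
  z <- render_lattice_field(p)
  h <- p$image_size[1]; w <- p$image_size[2]
  if (any(p$tilt_plane != 0)) {
    z <- z + outer(p$tilt_plane[2] * (seq_len(h) - 1),
                   p$tilt_plane[1] * (seq_len(w) - 1), `+`)
  }
  if (p$roughness_sd > 0) {
    z <- z + with_seed(p$seed, matrix(stats::rnorm(h * w, 0, p$roughness_sd), h, w))
  }
  list(topograph = topograph(z, nm_per_px = p$nm_per_px),
       truth = list(a_length = p$a_length, c_length = p$c_length,
                    cell_angle = p$cell_angle))
}

#' Rectangular region of a mixed-phase topograph
#'
#' @param rows,cols Inclusive 1-based pixel bounds, `c(first, last)`.
#' @param lattice A [lattice_params()] describing the phase inside the
#'   rectangle.
#' @return Object of class `region_spec`.
#' @export
region_spec <- function(rows, cols, lattice) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (length(rows) != 2L || length(cols) != 2L || rows[1] > rows[2] ||
      cols[1] > cols[2] || rows[1] < 1L || cols[1] < 1L) {
    stop("invalid region rectangle", call. = FALSE)
  }
  if (!inherits(lattice, "lattice_params")) lattice <- do.call(lattice_params, lattice)
  structure(list(rows = rows, cols = cols, lattice = lattice),
            class = "region_spec")
}

#' Generate a mixed-phase topograph
#'
#' Fills each rectangle with its own lattice, cross-fading over a
#' `blend_px`-pixel boundary, then adds a shared tilt plane and roughness.
#' Emulates an AFM frame caught mid-transition, where different parts of
#' the imaged area sit in different lattices.
#'
#' @param regions List of [region_spec()]; at least two, non-overlapping,
#'   inside the image.
#' @param image_size `c(rows, cols)` in px.
#' @param nm_per_px Calibration shared by all regions.
#' @param roughness_sd Global Gaussian height noise sd (nm).
#' @param tilt_plane Global `c(slope_x, slope_y)` in nm/px.
#' @param blend_px Cross-fade width at region boundaries (px, <= 2 by
#'   design).
#' @param seed Integer seed.
#' @return List with `topograph`, `regions` (the input), and `truth` (a
#'   `data.frame` of per-region designed cells).
#' @export
generate_mixed_topograph <- function(regions, image_size = c(256, 384),
                                     nm_per_px = 100 / 256,
                                     roughness_sd = 0, tilt_plane = c(0, 0),
                                     blend_px = 2, seed = 1L) {
  if (length(regions) < 2L) stop("need at least two regions", call. = FALSE)
  image_size <- rep_len(as.integer(image_size), 2L)
  for (r in regions) {
    if (r$rows[2] > image_size[1] || r$cols[2] > image_size[2]) {
      stop("region outside the image", call. = FALSE)
    }
  }
  occ <- matrix(0L, image_size[1], image_size[2])
  for (r in regions) {
    occ[r$rows[1]:r$rows[2], r$cols[1]:r$cols[2]] <-
      occ[r$rows[1]:r$rows[2], r$cols[1]:r$cols[2]] + 1L
  }
  if (any(occ > 1L)) stop("regions overlap", call. = FALSE)

  ramp_weight <- function(idx, lo, hi, blend) {
    # 1 inside [lo, hi], linear decay to 0 over `blend` px outside
    w <- pmin(1, pmax(0, 1 - (lo - idx) / max(blend, 1e-9))) *
      pmin(1, pmax(0, 1 - (idx - hi) / max(blend, 1e-9)))
    w
  }
  num <- matrix(0, image_size[1], image_size[2])
  den <- matrix(0, image_size[1], image_size[2])
  for (r in regions) {
    f <- render_lattice_field(r$lattice, image_size)
    wr <- ramp_weight(seq_len(image_size[1]), r$rows[1], r$rows[2], blend_px)
    wc <- ramp_weight(seq_len(image_size[2]), r$cols[1], r$cols[2], blend_px)
    wmat <- outer(wr, wc)
    num <- num + wmat * f
    den <- den + wmat
  }
  z <- ifelse(den > 0, num / pmax(den, 1e-12), 0)
  if (any(tilt_plane != 0)) {
    z <- z + outer(tilt_plane[2] * (seq_len(image_size[1]) - 1),
                   tilt_plane[1] * (seq_len(image_size[2]) - 1), `+`)
  }
  if (roughness_sd > 0) {
    z <- z + with_seed(seed, matrix(stats::rnorm(length(z), 0, roughness_sd),
                                    nrow(z), ncol(z)))
  }
  truth <- do.call(rbind, lapply(seq_along(regions), function(i) {
    l <- regions[[i]]$lattice
    data.frame(region = i, a_length = l$a_length, c_length = l$c_length,
               cell_angle = l$cell_angle)
  }))
  list(topograph = topograph(z, nm_per_px = nm_per_px),
       regions = regions, truth = truth)
}
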