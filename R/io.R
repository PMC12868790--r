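# TIFF + JSON-sidecar I/O.
#
# The tiff package stores 32-bit float samples clamped to [0, 1], so float
# channels are rescaled per page with the affine (offset, scale) recorded in
# the sidecar; integer photon counts are stored as 16-bit unsigned. Axis
# order is (row, col, time) with the pixel origin top-left, 0-based bins.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    stop(sprintf("missing metadata sidecar '%s'; refusing to guess metadata",
                 sp))
  }
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

# encode a list of float matrices as [0,1] pages + per-page offset/scale
encode_float_pages <- function(mats) {
  enc <- lapply(mats, function(m) {
    m[is.na(m)] <- NaN
    lo <- suppressWarnings(min(m, na.rm = TRUE))
    hi <- suppressWarnings(max(m, na.rm = TRUE))
    if (!is.finite(lo)) { lo <- 0; hi <- 1 }
    scale <- max(hi - lo, 1e-30)
    p <- (m - lo) / scale
    p[!is.finite(p)] <- 0
    list(page = p, offset = lo, scale = scale)
  })
  list(pages = lapply(enc, `[[`, "page"),
       offset = vapply(enc, `[[`, numeric(1), "offset"),
       scale = vapply(enc, `[[`, numeric(1), "scale"))
}

decode_float_pages <- function(pages, offset, scale, na_mask = NULL) {
  lapply(seq_along(pages), function(i) {
    m <- pages[[i]] * scale[i] + offset[i]
    if (!is.null(na_mask)) m[na_mask] <- NA_real_
    m
  })
}

#' Write / read a decay stack as multi-page TIFF + JSON sidecar
#'
#' Pages are time bins. Integer counts are stored losslessly as 16-bit
#' unsigned samples (counts above 65535 are an error); real-valued
#' expectation stacks are stored as 32-bit float with a per-page affine
#' rescaling recorded in the sidecar. The sidecar carries the acquisition
#' metadata (`rep_rate_hz`, `n_bins`, `bin_width_ns`, irf/distortion
#' parameters, `z_um`, `channel`) and is required for reading — a stack is
#' never reconstructed from guessed metadata.
#'
#' @param stack A [decay_stack()].
#' @param path Output TIFF path (sidecar written to `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_decay_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "decay_stack"))
  acq <- stack$acquisition
  d <- dim(stack$counts)
  mats <- lapply(seq_len(d[3]), function(b) stack$counts[, , b])
  integerish <- all(stack$counts >= 0) &&
    max(abs(stack$counts - round(stack$counts))) == 0
  meta <- list(
    kind = "decay_stack",
    rep_rate_hz = acq$rep_rate, n_bins = acq$n_bins,
    bin_width_ns = acq$bin_width, irf_sigma_ns = acq$irf_sigma,
    phase_offset_rad = acq$phase_offset, mod_loss = acq$mod_loss,
    z_um = stack$z, channel = stack$channel_label,
    shape = d[1:2], axis_order = "row,col,time", origin = "top-left 0-based"
  )
  if (integerish) {
    if (max(stack$counts) > 65535) {
      stop("integer counts exceed 65535; cannot store as 16-bit")
    }
    meta$storage <- list(mode = "uint16")
    tiff::writeTIFF(lapply(mats, function(m) m / 65535), path,
                    bits.per.sample = 16L, reduce = FALSE)
  } else {
    enc <- encode_float_pages(mats)
    meta$storage <- list(mode = "float32", offset = enc$offset,
                         scale = enc$scale)
    suppressWarnings(tiff::writeTIFF(enc$pages, path,
                                     bits.per.sample = 32L, reduce = FALSE))
  }
  write_sidecar(path, meta)
  invisible(path)
}

#' @rdname write_decay_tiff
#' @return For `read_decay_tiff`: the reconstructed [decay_stack()].
#' @export
read_decay_tiff <- function(path) {
  meta <- read_sidecar(path)
  acq <- acquisition_model(
    rep_rate = meta$rep_rate_hz, n_bins = meta$n_bins,
    irf_sigma = meta$irf_sigma_ns, phase_offset = meta$phase_offset_rad,
    mod_loss = meta$mod_loss
  )
  uint <- identical(meta$storage$mode, "uint16")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = uint)
  if (length(pages) != meta$n_bins) {
    stop(sprintf("TIFF has %d pages but sidecar declares %d time bins",
                 length(pages), meta$n_bins))
  }
  if (!uint) {
    pages <- decode_float_pages(pages, meta$storage$offset,
                                meta$storage$scale)
  }
  d <- dim(pages[[1]])
  counts <- array(unlist(pages, use.names = FALSE),
                  c(d[1], d[2], length(pages)))
  decay_stack(counts, acq,
              z = if (is.null(meta$z_um)) NA_real_ else meta$z_um,
              channel_label = meta$channel)
}

#' Write / read a phasor field as multi-channel float TIFF + sidecar
#'
#' Channels (pages) are `g` then `s` per harmonic, followed by the intensity
#' image; undefined pixels are restored to `NA` via the intensity map. The
#' sidecar records harmonics, the calibrated flag, calibration factors (if
#' any) and the acquisition metadata.
#'
#' @param field A [phasor_field()].
#' @param path Output TIFF path.
#' @return `path` invisibly; for `read_phasor_tiff`, the [phasor_field()].
#' @export
write_phasor_tiff <- function(field, path) {
  stopifnot(inherits(field, "phasor_field"))
  H <- length(field$harmonics)
  mats <- list()
  chan <- character(0)
  for (j in seq_len(H)) {
    mats <- c(mats, list(field$g[, , j], field$s[, , j]))
    chan <- c(chan, sprintf("g%d", field$harmonics[j]),
              sprintf("s%d", field$harmonics[j]))
  }
  mats <- c(mats, list(field$intensity))
  chan <- c(chan, "intensity")
  enc <- encode_float_pages(mats)
  acq <- field$acquisition
  meta <- list(
    kind = "phasor_field", channels = chan,
    harmonics = field$harmonics, calibrated = field$calibrated,
    rep_rate_hz = acq$rep_rate, n_bins = acq$n_bins,
    irf_sigma_ns = acq$irf_sigma, phase_offset_rad = acq$phase_offset,
    mod_loss = acq$mod_loss,
    storage = list(mode = "float32", offset = enc$offset, scale = enc$scale),
    axis_order = "row,col", origin = "top-left 0-based"
  )
  if (!is.null(field$calibration)) {
    cal <- field$calibration
    meta$calibration <- list(
      m = cal$m, phi = cal$phi, harmonics = cal$harmonics,
      reference_name = cal$reference_name, reference_tau = cal$reference_tau
    )
  }
  suppressWarnings(tiff::writeTIFF(enc$pages, path,
                                   bits.per.sample = 32L, reduce = FALSE))
  write_sidecar(path, meta)
  invisible(path)
}

#' @rdname write_phasor_tiff
#' @export
read_phasor_tiff <- function(path) {
  meta <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$channels)) {
    stop(sprintf("TIFF has %d pages but sidecar declares %d channels",
                 length(pages), length(meta$channels)))
  }
  pages <- decode_float_pages(pages, meta$storage$offset, meta$storage$scale)
  names(pages) <- meta$channels
  acq <- acquisition_model(
    rep_rate = meta$rep_rate_hz, n_bins = meta$n_bins,
    irf_sigma = meta$irf_sigma_ns, phase_offset = meta$phase_offset_rad,
    mod_loss = meta$mod_loss
  )
  N <- pages[["intensity"]]
  H <- length(meta$harmonics)
  d <- dim(N)
  g <- array(NA_real_, c(d, H))
  s <- array(NA_real_, c(d, H))
  undef <- N == 0
  for (j in seq_len(H)) {
    gm <- pages[[sprintf("g%d", meta$harmonics[j])]]
    sm <- pages[[sprintf("s%d", meta$harmonics[j])]]
    gm[undef] <- NA_real_
    sm[undef] <- NA_real_
    g[, , j] <- gm
    s[, , j] <- sm
  }
  out <- phasor_field(g, s, N, meta$harmonics,
                      calibrated = isTRUE(meta$calibrated),
                      acquisition = acq)
  if (!is.null(meta$calibration)) {
    out$calibration <- structure(
      list(m = meta$calibration$m, phi = meta$calibration$phi,
           harmonics = meta$calibration$harmonics,
           reference_name = meta$calibration$reference_name,
           reference_tau = meta$calibration$reference_tau),
      class = "calibration_factors")
  }
  out
}

#' Write / read a fraction field as multi-channel float TIFF + sidecar
#'
#' One page per component plus the intensity image; component names and
#' lifetimes live in the sidecar.
#'
#' @param fractions A [fraction_field()].
#' @param path Output TIFF path.
#' @return `path` invisibly; for `read_fraction_tiff`, the field.
#' @export
write_fraction_tiff <- function(fractions, path) {
  stopifnot(inherits(fractions, "fraction_field"))
  k <- length(fractions$names)
  mats <- lapply(seq_len(k), function(j) fractions$fractions[, , j])
  mats <- c(mats, list(fractions$intensity))
  enc <- encode_float_pages(mats)
  meta <- list(
    kind = "fraction_field",
    components = fractions$names,
    tau_ns = if (!is.null(fractions$components)) {
      fractions$components$tau
    } else {
      NULL
    },
    storage = list(mode = "float32", offset = enc$offset, scale = enc$scale),
    axis_order = "row,col", origin = "top-left 0-based"
  )
  suppressWarnings(tiff::writeTIFF(enc$pages, path,
                                   bits.per.sample = 32L, reduce = FALSE))
  write_sidecar(path, meta)
  invisible(path)
}

#' @rdname write_fraction_tiff
#' @export
read_fraction_tiff <- function(path) {
  meta <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  k <- length(meta$components)
  if (length(pages) != k + 1L) {
    stop(sprintf("TIFF has %d pages but sidecar declares %d components + intensity",
                 length(pages), k))
  }
  pages <- decode_float_pages(pages, meta$storage$offset, meta$storage$scale)
  N <- pages[[k + 1L]]
  d <- dim(N)
  fr <- array(NA_real_, c(d, k))
  undef <- N == 0
  for (j in seq_len(k)) {
    m <- pages[[j]]
    m[undef] <- NA_real_
    fr[, , j] <- m
  }
  fraction_field(fr, meta$components, N)
}

#' Write / read a pixel mask as 8-bit TIFF (0/255) + provenance sidecar
#'
#' @param mask A [pixel_mask()].
#' @param path Output TIFF path.
#' @return `path` invisibly; for `read_mask_tiff`, the [pixel_mask()].
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "pixel_mask"))
  tiff::writeTIFF(mask$mask * 1.0, path, bits.per.sample = 8L)
  write_sidecar(path, list(kind = "pixel_mask",
                           provenance = mask$provenance))
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  meta <- read_sidecar(path)
  m <- tiff::readTIFF(path)
  pixel_mask(m > 0.5, meta$provenance)
}

#' Phasor-plot rendering
#'
#' Builds the 2-D histogram of pixel density over the `(g, s)` window
#' `[0, 1] x [0, 0.6]`, draws the universal semicircle
#' \eqn{g^2 + s^2 = g} and, optionally, the component vertices with the
#' connecting tetragon, as a deterministic RGB raster (no graphics device).
#'
#' @param field A [phasor_field()].
#' @param n Harmonic to plot.
#' @param component_overlay Optional [component_set()] to overlay.
#' @param bins Histogram cells per axis (default 256).
#' @return A list with `histogram` (bins x bins counts, rows = s descending),
#'   `g_breaks`, `s_breaks`, and `rgb` (raster array, rows x cols x 3).
#' @export
render_phasor_plot <- function(field, n = 1L, component_overlay = NULL,
                               bins = 256L) {
  stopifnot(inherits(field, "phasor_field"))
  j <- harmonic_slice(field, n)
  g <- as.vector(field$g[, , j])
  s <- as.vector(field$s[, , j])
  ok <- !is.na(g) & !is.na(s)
  gb <- seq(0, 1, length.out = bins + 1L)
  sb <- seq(0, 0.6, length.out = bins + 1L)
  gi <- findInterval(g[ok], gb, rightmost.closed = TRUE)
  si <- findInterval(s[ok], sb, rightmost.closed = TRUE)
  inside <- gi >= 1L & gi <= bins & si >= 1L & si <= bins
  H <- matrix(0L, bins, bins) # [s_bin, g_bin], s increasing with row index
  if (any(inside)) {
    tab <- table(factor(si[inside], levels = seq_len(bins)),
                 factor(gi[inside], levels = seq_len(bins)))
    H <- matrix(as.integer(tab), bins, bins)
  }
  # density ramp white -> dark blue
  dmax <- max(H)
  dn <- if (dmax > 0) H / dmax else H
  rgb <- array(1, c(bins, bins, 3L))
  rgb[, , 1] <- 1 - dn
  rgb[, , 2] <- 1 - dn
  rgb[, , 3] <- 1 - 0.2 * dn
  # universal semicircle in black
  th <- seq(0, pi, length.out = 4L * bins)
  cg <- 0.5 + 0.5 * cos(th)
  cs <- 0.5 * sin(th)
  cgi <- pmin(pmax(findInterval(cg, gb, rightmost.closed = TRUE), 1L), bins)
  csi <- findInterval(cs, sb, rightmost.closed = TRUE)
  on <- csi >= 1L & csi <= bins
  for (ch in 1:3) rgb[cbind(csi[on], cgi[on], ch)] <- 0
  if (!is.null(component_overlay)) {
    stopifnot(inherits(component_overlay, "component_set"))
    vg <- component_overlay[[sprintf("g%d", n)]]
    vs <- component_overlay[[sprintf("s%d", n)]]
    k <- length(vg)
    # tetragon edges between consecutive vertices (closed polygon)
    ordv <- order(atan2(vs - mean(vs), vg - mean(vg)))
    for (e in seq_len(k)) {
      a <- ordv[e]; b <- ordv[if (e == k) 1L else e + 1L]
      tt <- seq(0, 1, length.out = 2L * bins)
      lg <- vg[a] + tt * (vg[b] - vg[a])
      ls <- vs[a] + tt * (vs[b] - vs[a])
      lgi <- findInterval(lg, gb, rightmost.closed = TRUE)
      lsi <- findInterval(ls, sb, rightmost.closed = TRUE)
      onl <- lgi >= 1L & lgi <= bins & lsi >= 1L & lsi <= bins
      rgb[cbind(lsi[onl], lgi[onl], 1L)] <- 0.6
      rgb[cbind(lsi[onl], lgi[onl], 2L)] <- 0.6
      rgb[cbind(lsi[onl], lgi[onl], 3L)] <- 0.6
    }
    # vertices as red 3x3 dots
    for (v in seq_len(k)) {
      vgi <- pmin(pmax(findInterval(vg[v], gb, rightmost.closed = TRUE), 2L),
                  bins - 1L)
      vsi <- pmin(pmax(findInterval(vs[v], sb, rightmost.closed = TRUE), 2L),
                  bins - 1L)
      rows <- (vsi - 1L):(vsi + 1L)
      cols <- (vgi - 1L):(vgi + 1L)
      rgb[rows, cols, 1] <- 1
      rgb[rows, cols, 2] <- 0
      rgb[rows, cols, 3] <- 0
    }
  }
  # flip so s increases upward in the written image
  raster <- rgb[rev(seq_len(bins)), , , drop = FALSE]
  list(histogram = H, g_breaks = gb, s_breaks = sb, rgb = raster)
}

#' Save an RGB array as PNG
#'
#' @param img Rows x cols x 3 array in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
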