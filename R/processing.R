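#' Pixel inclusion mask
#'
#' @param mask Logical matrix, `TRUE` = included.
#' @param provenance Text describing the rule that built the mask.
#' @return An object of class `pixel_mask`.
#' @export
pixel_mask <- function(mask, provenance = "manual") {
  stopifnot(is.logical(mask), is.matrix(mask))
  structure(list(mask = mask, provenance = provenance), class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask> %d x %d, %d included (%.1f%%)\n  provenance: %s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask), x$provenance))
  invisible(x)
}

#' Combine masks by logical AND
#'
#' @param ... `pixel_mask` objects of identical shape.
#' @return A `pixel_mask` including only pixels included by every input.
#' @export
combine_masks <- function(...) {
  ms <- list(...)
  stopifnot(length(ms) >= 1L, all(vapply(ms, inherits, TRUE, "pixel_mask")))
  out <- Reduce(`&`, lapply(ms, `[[`, "mask"))
  pixel_mask(out, paste(vapply(ms, `[[`, "", "provenance"), collapse = " AND "))
}

# block indices for factor-f binning, cropping the trailing remainder
binning_extent <- function(nr, nc, factor, what) {
  kr <- nr %/% factor
  kc <- nc %/% factor
  if (kr * factor != nr || kc * factor != nc) {
    warning(sprintf(
      "%s: factor %d does not divide %d x %d; dropping trailing %d row(s) and %d col(s)",
      what, factor, nr, nc, nr - kr * factor, nc - kc * factor))
  }
  c(kr, kc)
}

# sum non-overlapping f x f blocks of a matrix (cropped to kr*f x kc*f)
block_sum <- function(m, factor, kr, kc) {
  m <- m[seq_len(kr * factor), seq_len(kc * factor), drop = FALSE]
  a <- array(m, c(factor, kr, factor, kc))
  colSums(aperm(a, c(1, 3, 2, 4)), dims = 2L)
}

#' Spatial binning (downsampling) of stacks and phasor fields
#'
#' Sums non-overlapping `factor` x `factor` pixel blocks to raise the photon
#' count per (binned) pixel without discarding information — e.g. a
#' 1024 x 1024 raster binned by the default factor 4 becomes the 256 x 256
#' analysis raster. For a [decay_stack()] the counts are summed per time bin
#' (photons conserved exactly over the retained region). For a
#' [phasor_field()] the underlying per-pixel Fourier numerators and
#' denominators are summed — i.e. a photon-weighted mean of `(g, s)`, never
#' an unweighted average — so binning commutes with the phasor transform.
#' A `factor` that does not divide the lateral dimensions drops the trailing
#' remainder rows/columns with a warning.
#'
#' @param x A `decay_stack` or `phasor_field`.
#' @param factor Integer block size (>= 1); 1 is the identity.
#' @return Object of the same class, downsampled.
#' @export
bin_spatial <- function(x, factor = 4L) {
  if (factor < 1) stop("factor must be >= 1")
  factor <- as.integer(factor)
  UseMethod("bin_spatial")
}

#' @export
bin_spatial.decay_stack <- function(x, factor = 4L) {
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  d <- dim(x$counts)
  k <- binning_extent(d[1], d[2], factor, "bin_spatial(decay_stack)")
  out <- array(0, c(k[1], k[2], d[3]))
  for (b in seq_len(d[3])) {
    out[, , b] <- block_sum(x$counts[, , b], factor, k[1], k[2])
  }
  x$counts <- out
  x
}

#' @export
bin_spatial.phasor_field <- function(x, factor = 4L) {
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  d <- dim(x$g)
  k <- binning_extent(d[1], d[2], factor, "bin_spatial(phasor_field)")
  N <- block_sum(x$intensity, factor, k[1], k[2])
  g <- array(NA_real_, c(k[1], k[2], d[3]))
  s <- array(NA_real_, c(k[1], k[2], d[3]))
  ok <- N != 0
  for (j in seq_len(d[3])) {
    num_g <- x$g[, , j] * x$intensity
    num_s <- x$s[, , j] * x$intensity
    num_g[x$intensity == 0] <- 0 # undefined pixels carry no photons
    num_s[x$intensity == 0] <- 0
    gg <- block_sum(num_g, factor, k[1], k[2])
    ss <- block_sum(num_s, factor, k[1], k[2])
    gg[ok] <- gg[ok] / N[ok]; gg[!ok] <- NA_real_
    ss[ok] <- ss[ok] / N[ok]; ss[!ok] <- NA_real_
    g[, , j] <- gg
    s[, , j] <- ss
  }
  x$g <- g
  x$s <- s
  x$intensity <- N
  x
}

# reflect-pad a matrix by w pixels on each side
reflect_pad <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(w, nr))), seq_len(nr),
          nr + 1 - seq_len(min(w, nr)))
  ci <- c(rev(seq_len(min(w, nc))), seq_len(nc),
          nc + 1 - seq_len(min(w, nc)))
  m[ri, ci, drop = FALSE]
}

# NA-excluding k x k median filter with reflection edges
median_filter_matrix <- function(m, k) {
  w <- k %/% 2L
  p <- reflect_pad(m, w)
  nr <- nrow(m); nc <- ncol(m)
  win <- matrix(NA_real_, nr * nc, k * k)
  idx <- 1L
  for (dc in 0:(k - 1L)) {
    for (dr in 0:(k - 1L)) {
      win[, idx] <- as.vector(p[dr + seq_len(nr), dc + seq_len(nc)])
      idx <- idx + 1L
    }
  }
  out <- apply(win, 1L, stats::median, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_ # windows that were all-NA
  matrix(out, nr, nc)
}

#' Median filter in the phasor domain
#'
#' Applies an odd-sized median filter (default 3 x 3) independently to each
#' phasor channel (`g` and `s` at every harmonic) while leaving the spatial
#' intensity image bit-identical. Undefined pixels are excluded from the
#' windows; edges are handled by reflection so the field keeps its size.
#' This reduces phasor spread (shot-noise scatter) without touching the
#' intensity data, and may be applied for several passes.
#'
#' @param field A calibrated [phasor_field()].
#' @param kernel Odd window size (default 3).
#' @param passes Number of filter passes (default 1).
#' @return The filtered `phasor_field`.
#' @export
median_filter_phasor <- function(field, kernel = 3L, passes = 1L) {
  stopifnot(inherits(field, "phasor_field"))
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L) stop("kernel size must be odd")
  if (!field$calibrated) stop("median_filter_phasor expects a calibrated field")
  d <- dim(field$g)[1:2]
  for (p in seq_len(passes)) {
    for (j in seq_len(dim(field$g)[3])) {
      undef <- is.na(array(field$g[, , j], d))
      gm <- median_filter_matrix(array(field$g[, , j], d), kernel)
      sm <- median_filter_matrix(array(field$s[, , j], d), kernel)
      gm[undef] <- NA_real_ # undefined pixels stay undefined
      sm[undef] <- NA_real_
      field$g[, , j] <- gm
      field$s[, , j] <- sm
    }
  }
  field
}

#' Photon-count threshold mask
#'
#' Includes pixels whose intensity is at least `min_photons` and whose phasor
#' is defined. The default of 30 photons keeps the unmixing conditioned while
#' still exercising low-signal pixels after 4 x 4 binning of a ~225
#' photons/pixel acquisition.
#'
#' @param field A [phasor_field()].
#' @param min_photons Minimum photons per (possibly binned) pixel (>= 0).
#' @return A [pixel_mask()].
#' @export
threshold_mask <- function(field, min_photons = 30) {
  stopifnot(inherits(field, "phasor_field"), min_photons >= 0)
  defined <- !is.na(field$g[, , 1])
  pixel_mask(field$intensity >= min_photons & defined,
             sprintf("intensity >= %g and phasor defined", min_photons))
}

#' Exclusion mask for large keratin-rich features
#'
#' Finds connected components (8-connectivity) of pixels whose keratin
#' fraction exceeds `f_threshold` and marks components of at least `min_area`
#' pixels for exclusion — the rule used to remove hairs and other large
#' keratin-rich structures so they do not dominate NADH distribution
#' statistics. Smaller keratin-rich specks are retained.
#'
#' @param fractions A `fraction_field` (see [unmix()]) containing a
#'   component named `"keratin"`.
#' @param f_threshold Keratin fraction above which a pixel is keratin-rich.
#' @param min_area Minimum component area (pixels) to exclude.
#' @return A [pixel_mask()] where `TRUE` marks pixels to EXCLUDE.
#' @export
mask_large_keratin_features <- function(fractions, f_threshold = 0.5,
                                        min_area = 200L) {
  stopifnot(inherits(fractions, "fraction_field"))
  kj <- match("keratin", fractions$names)
  if (is.na(kj)) stop("fraction field has no keratin component")
  f <- fractions$fractions[, , kj]
  B <- !is.na(f) & f > f_threshold
  excl <- matrix(FALSE, nrow(B), ncol(B))
  if (any(B)) {
    lab <- label_components8(B)
    sizes <- tabulate(lab[B])
    big <- which(sizes >= min_area)
    if (length(big)) excl <- matrix(lab %in% big, nrow(B), ncol(B))
  }
  pixel_mask(excl, sprintf(
    "keratin fraction > %g in 8-connected components of area >= %d",
    f_threshold, as.integer(min_area)))
}

# label 8-connected components of a logical matrix; 0 = background
label_components8 <- function(B) {
  nr <- nrow(B); nc <- ncol(B)
  idx <- which(B)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  vid <- matrix(0L, nr, nc)
  vid[idx] <- seq_along(idx)
  edges <- integer(0)
  for (shift in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    r2 <- r + shift[1]; c2 <- c + shift[2]
    ok <- r2 >= 1L & r2 <= nr & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- B[nb]
    if (any(hit)) {
      edges <- c(edges, rbind(vid[idx[ok][hit]], vid[nb[hit]]))
    }
  }
  gr <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) gr <- igraph::add_edges(gr, edges)
  comp <- igraph::components(gr)$membership
  lab[idx] <- as.integer(comp)
  lab
}
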