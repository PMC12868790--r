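#' Component set for phasor unmixing
#'
#' Named fluorophores with reference mono-exponential lifetimes and their
#' phasor coordinates at harmonics 1 and 2 (derived with
#' [analytic_phasor()], hence exactly on the universal circle). The default
#' set is the four epidermal components used throughout the analysis:
#' free NADH (0.4 ns), protein-bound NADH (3.4 ns), keratin (1.1 ns) and
#' melanin (0.0 ns, an ultrafast delta-like emitter whose phasor sits at the
#' (1, 0) vertex at every harmonic).
#'
#' @param names Character vector of unique component names (2 to 4).
#' @param taus Lifetimes in ns, same length as `names`.
#' @param acq An [acquisition_model()] (sets the angular frequency).
#' @return An object of class `component_set`: data frame with columns
#'   `name`, `tau`, `g1`, `s1`, `g2`, `s2`, plus the acquisition model as an
#'   attribute.
#' @export
#' @examples
#' default_components()
component_set <- function(names, taus, acq = acquisition_model()) {
  stopifnot(length(names) == length(taus),
            length(names) >= 2L, length(names) <= 4L)
  if (anyDuplicated(names)) stop("component names must be unique")
  if (any(taus < 0)) stop("component lifetimes must be >= 0")
  p1 <- analytic_phasor(taus, 1L, acq)
  p2 <- analytic_phasor(taus, 2L, acq)
  out <- data.frame(name = as.character(names), tau = as.numeric(taus),
                    g1 = p1$g, s1 = p1$s, g2 = p2$g, s2 = p2$s,
                    stringsAsFactors = FALSE)
  attr(out, "acquisition") <- acq
  class(out) <- c("component_set", "data.frame")
  out
}

#' @rdname component_set
#' @export
default_components <- function(acq = acquisition_model()) {
  component_set(
    names = c("free_nadh", "bound_nadh", "keratin", "melanin"),
    taus = c(0.4, 3.4, 1.1, 0.0),
    acq = acq
  )
}

#' Unmixing design matrix
#'
#' Stacks the component phasor coordinates at harmonics 1 and 2 with a
#' normalization row of ones: rows `g1, s1, g2, s2, 1`, one column per
#' component (in set order). The matrix has full column rank whenever the
#' component lifetimes are distinct.
#'
#' @param components A [component_set()].
#' @return A 5 x k numeric matrix with component names as column names.
#' @export
component_matrix <- function(components) {
  stopifnot(inherits(components, "component_set"))
  M <- rbind(components$g1, components$s1,
             components$g2, components$s2,
             rep(1, nrow(components)))
  dimnames(M) <- list(c("g1", "s1", "g2", "s2", "one"), components$name)
  if (qr(M)$rank < ncol(M)) {
    dup <- components$name[duplicated(components$tau) |
                             duplicated(components$tau, fromLast = TRUE)]
    stop(sprintf("component matrix is rank deficient (colliding: %s)",
                 paste(unique(dup), collapse = ", ")))
  }
  M
}

#' Fraction field constructor
#'
#' @param fractions Row x col x k array of fractional intensities.
#' @param names Component names (length k).
#' @param intensity Row x col matrix of per-pixel photons.
#' @param components The [component_set()] used, if any.
#' @param mask The [pixel_mask()] applied, if any.
#' @return An object of class `fraction_field`.
#' @export
fraction_field <- function(fractions, names, intensity,
                           components = NULL, mask = NULL) {
  stopifnot(length(dim(fractions)) == 3L,
            dim(fractions)[3] == length(names),
            all(dim(intensity) == dim(fractions)[1:2]))
  structure(list(
    fractions = fractions, names = as.character(names),
    intensity = intensity, components = components, mask = mask
  ), class = "fraction_field")
}

#' @export
print.fraction_field <- function(x, ...) {
  d <- dim(x$fractions)
  cat(sprintf("<fraction_field> %d x %d pixels, components: %s\n",
              d[1], d[2], paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Pixel-wise multicomponent unmixing from two-harmonic phasors
#'
#' Solves, for every included pixel, the linear system relating the measured
#' calibrated phasor coordinates at harmonics 1 and 2 to the fraction-
#' weighted sum of the component phasors. The normalization
#' \eqn{\sum_i f_i = 1} is enforced exactly and the four phasor equations
#' are solved by least squares within that affine subspace. Fractions may be
#' negative: a phasor that falls outside the tetragon spanned by the
#' component vertices (typical of low-SNR pixels) yields negative fractions
#' by construction, and these are legal, diagnostic outputs. The
#' per-component photon map is `f_i * N`.
#'
#' @param field A calibrated [phasor_field()] with harmonics 1 and 2.
#' @param components A [component_set()].
#' @param mask Optional [pixel_mask()]; excluded pixels come back `NA`.
#' @return A [fraction_field()].
#' @export
unmix <- function(field, components = default_components(), mask = NULL) {
  stopifnot(inherits(field, "phasor_field"))
  if (!field$calibrated) stop("field must be calibrated before unmixing")
  j1 <- harmonic_slice(field, 1L)
  j2 <- harmonic_slice(field, 2L)
  M <- component_matrix(components)
  A <- M[1:4, , drop = FALSE]
  k <- ncol(A)
  d <- dim(field$g)
  B <- matrix(rbind(as.vector(field$g[, , j1]), as.vector(field$s[, , j1]),
                    as.vector(field$g[, , j2]), as.vector(field$s[, , j2])),
              nrow = 4L)
  ok <- !is.na(B[1L, ])
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "pixel_mask"),
              all(dim(mask$mask) == d[1:2]))
    ok <- ok & as.vector(mask$mask)
  }
  # f = c + Z u with c the simplex centre and Z a basis of the sum-zero
  # subspace: the constraint sum(f) = 1 holds exactly for any u.
  cc <- rep(1 / k, k)
  Z <- rbind(diag(k - 1L), rep(-1, k - 1L))
  AZ <- A %*% Z
  rhs <- B[, ok, drop = FALSE] - as.vector(A %*% cc)
  U <- solve(crossprod(AZ), crossprod(AZ, rhs))
  Fok <- cc + Z %*% U
  out <- matrix(NA_real_, k, d[1] * d[2])
  out[, ok] <- Fok
  fraction_field(
    array(t(out), c(d[1], d[2], k)),
    names = components$name,
    intensity = field$intensity,
    components = components,
    mask = mask
  )
}

#' Per-component photon maps
#'
#' @param fractions A [fraction_field()].
#' @return Row x col x k array of `f_i * N` photon counts.
#' @export
component_photons <- function(fractions) {
  stopifnot(inherits(fractions, "fraction_field"))
  sweep(fractions$fractions, c(1, 2), fractions$intensity, `*`)
}

#' Protein-bound NADH fraction of total NADH
#'
#' Computes per pixel the ratio of fluorescence attributed to protein-bound
#' NADH over the total NADH fluorescence,
#' \eqn{f_{bound}/(f_{bound} + f_{free})} — the label-free metabolic readout
#' (bound share drops as cells shift toward glycolysis). Pixels where the
#' total NADH fraction is at or below `eps` are returned `NA`.
#'
#' @param fractions A [fraction_field()] containing components `free_nadh`
#'   and `bound_nadh`.
#' @param eps Validity floor for the denominator (default 1e-6).
#' @return Matrix of ratios, `NA` where invalid.
#' @export
bound_nadh_ratio <- function(fractions, eps = 1e-6) {
  stopifnot(inherits(fractions, "fraction_field"))
  jb <- match("bound_nadh", fractions$names)
  jf <- match("free_nadh", fractions$names)
  if (is.na(jb) || is.na(jf)) {
    stop("fraction field must contain free_nadh and bound_nadh components")
  }
  d <- dim(fractions$fractions)[1:2]
  fb <- array(fractions$fractions[, , jb], d)
  ff <- array(fractions$fractions[, , jf], d)
  den <- fb + ff
  ratio <- fb / den
  ratio[!is.na(den) & den <= eps] <- NA_real_
  ratio
}

#' Merged colour-coded fraction map
#'
#' Renders the direct sum of the components: per pixel,
#' `RGB = sum_i clip(f_i, 0, 1) * color_i`, scaled by the normalized
#' intensity, so a single-component pixel shows exactly that component's
#' colour at full intensity and a zero-intensity pixel is black.
#'
#' @param fractions A [fraction_field()].
#' @param colors Named list (or k x 3 matrix) of RGB triples in `[0, 1]`,
#'   one per component.
#' @return Row x col x 3 array with values in `[0, 1]`.
#' @export
combined_fraction_map <- function(fractions, colors = default_colors()) {
  stopifnot(inherits(fractions, "fraction_field"))
  if (is.list(colors)) {
    missing <- setdiff(fractions$names, names(colors))
    if (length(missing)) {
      stop(sprintf("no color for component(s): %s",
                   paste(missing, collapse = ", ")))
    }
    colors <- do.call(rbind, colors[fractions$names])
  }
  stopifnot(nrow(colors) == length(fractions$names), ncol(colors) == 3L)
  d <- dim(fractions$fractions)
  Imax <- max(fractions$intensity)
  scale <- if (Imax > 0) fractions$intensity / Imax else fractions$intensity
  rgb <- array(0, c(d[1], d[2], 3L))
  for (j in seq_len(d[3])) {
    f <- pmin(pmax(fractions$fractions[, , j], 0), 1)
    f[is.na(f)] <- 0
    for (ch in 1:3) {
      rgb[, , ch] <- rgb[, , ch] + f * colors[j, ch] * scale
    }
  }
  pmin(rgb, 1)
}

#' @rdname combined_fraction_map
#' @export
default_colors <- function() {
  list(
    keratin = c(1, 0, 0),       # red
    melanin = c(0, 0, 1),       # blue
    bound_nadh = c(1, 1, 0),    # yellow
    free_nadh = c(0.5, 0, 0.5)  # purple
  )
}
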