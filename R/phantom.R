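#' Phantom specification
#'
#' Declares an epidermal phantom scenario: a preset naming the spatial and
#' compositional structure, the raster shape, nominal depths, the expected
#' photon budget per pixel and the RNG seed. Depth values are nominal labels
#' (micrometres) — the scenarios are defined by their composition ramps, not
#' by an optical model of attenuation with depth.
#'
#' Presets:
#' \describe{
#'   \item{`stratum_corneum`}{Keratin-dominated outermost layer with
#'     curvilinear high-keratin fold features.}
#'   \item{`depth_series_typeV`}{Highly pigmented skin: ground-truth melanin
#'     fraction increases monotonically with depth (toward the basal layer)
#'     while keratin decreases; the bound share of NADH decreases with depth
#'     (more glycolytic basal layers).}
#'   \item{`depth_series_typeIII`}{As type V with intermediate melanin.}
#'   \item{`depth_series_vitiligo`}{Melanin-free skin: melanin fraction at
#'     most 0.02 everywhere and a depth-constant bound-NADH share.}
#'   \item{`sk_horn_cysts`}{Seborrheic-keratosis scene: keratin-filled disks
#'     (fraction >= 0.8) embedded in a melanin-rich surround.}
#'   \item{`exvivo_pair`}{Two stacks ("0h", "6h") identical except that the
#'     bound share of NADH drops after six hours ex vivo; both contain
#'     hair-like large keratin-rich streaks.}
#' }
#'
#' @param preset One of the preset names above.
#' @param shape Integer (rows, cols).
#' @param depths Numeric z positions in micrometres (presets with a depth
#'   series default to five planes; single-scene presets to one).
#' @param mean_photons Expected photons per pixel (default 225, the midpoint
#'   of the ~200-250 photons/pixel typical of the clinical acquisitions).
#' @param seed Integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(preset, shape = c(128L, 128L), depths = NULL,
                         mean_photons = 225, seed = 1L) {
  presets <- c("stratum_corneum", "depth_series_typeV",
               "depth_series_typeIII", "depth_series_vitiligo",
               "sk_horn_cysts", "exvivo_pair")
  if (!preset %in% presets) {
    stop(sprintf("unknown preset '%s'; valid presets: %s",
                 preset, paste(presets, collapse = ", ")))
  }
  if (mean_photons <= 0) stop("mean_photons must be > 0")
  if (is.null(depths)) {
    depths <- switch(preset,
      stratum_corneum = 0,
      sk_horn_cysts = 65,
      exvivo_pair = c(0, 0),
      seq(0, 60, length.out = 5)
    )
  }
  if (preset == "exvivo_pair" && length(depths) != 2L) {
    stop("exvivo_pair uses exactly two planes (0 h and 6 h)")
  }
  structure(list(
    preset = preset, shape = as.integer(shape), depths = depths,
    mean_photons = mean_photons, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# smooth random field in [0, 1] with mean exactly 1/2: sum of seeded
# random-phase sinusoids, rescaled to range [0,1] then mean-centred.
smooth_field <- function(shape, n_waves = 6L) {
  rr <- matrix(rep(seq_len(shape[1]) / shape[1], shape[2]), shape[1])
  cc <- matrix(rep(seq_len(shape[2]) / shape[2], each = shape[1]), shape[1])
  f <- matrix(0, shape[1], shape[2])
  for (i in seq_len(n_waves)) {
    kx <- stats::runif(1, 0.5, 4)
    ky <- stats::runif(1, 0.5, 4)
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.5, 1)
    f <- f + amp * sin(2 * pi * (kx * rr + ky * cc) + ph)
  }
  f <- (f - min(f)) / (max(f) - min(f) + .Machine$double.eps)
  f - mean(f) + 0.5
}

# curvilinear fold/hair mask: sinusoidal ridges of given half-width (pixels)
curvilinear_mask <- function(shape, n_curves = 3L, width = 2) {
  rr <- matrix(rep(seq_len(shape[1]), shape[2]), shape[1])
  cc <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1])
  m <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(n_curves)) {
    r0 <- stats::runif(1, 0.15, 0.85) * shape[1]
    amp <- stats::runif(1, 0.05, 0.2) * shape[1]
    per <- stats::runif(1, 0.5, 1.5)
    ph <- stats::runif(1, 0, 2 * pi)
    center <- r0 + amp * sin(2 * pi * per * cc / shape[2] + ph)
    m <- m | abs(rr - center) <= width
  }
  m
}

# disk mask; radii scale with the raster, centres kept off the border
disk_mask <- function(shape, n_disks = 6L, r_range = NULL) {
  if (is.null(r_range)) {
    r_range <- c(max(3, round(min(shape) / 16)),
                 max(4, round(min(shape) / 9)))
  }
  rr <- matrix(rep(seq_len(shape[1]), shape[2]), shape[1])
  cc <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1])
  m <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(n_disks)) {
    rad <- stats::runif(1, r_range[1], r_range[2])
    r0 <- stats::runif(1, min(rad + 2, shape[1] / 2),
                       max(shape[1] - rad - 2, shape[1] / 2))
    c0 <- stats::runif(1, min(rad + 2, shape[2] / 2),
                       max(shape[2] - rad - 2, shape[2] / 2))
    m <- m | ((rr - r0)^2 + (cc - c0)^2 <= rad^2)
  }
  m
}

# assemble a (rows*cols) x 4 ground-truth fraction matrix in component
# order (free_nadh, bound_nadh, keratin, melanin); fractions sum to 1
compose_fractions <- function(keratin, melanin, rho) {
  tot <- keratin + melanin
  over <- tot > 0.95
  if (any(over)) {
    sc <- 0.95 / tot
    keratin[over] <- keratin[over] * sc[over]
    melanin[over] <- melanin[over] * sc[over]
  }
  nadh <- 1 - keratin - melanin
  cbind(free_nadh = as.vector((1 - rho) * nadh),
        bound_nadh = as.vector(rho * nadh),
        keratin = as.vector(keratin),
        melanin = as.vector(melanin))
}

#' Generate an epidermal phantom
#'
#' Builds, for each depth of the spec, a ground-truth composition map (per
#' pixel: fractions of free NADH, bound NADH, keratin and melanin summing to
#' 1) and the corresponding decay stack: the expected decay of each pixel is
#' the fraction-weighted sum of the component decay models scaled to
#' `mean_photons`, passed through the instrument distortion of `acq` and,
#' if `noise`, Poisson-sampled. Composition textures are shared across depths so the
#' per-depth means follow the programmed ramps exactly, making the preset
#' contracts (monotonic melanin, constant vitiligo share, ...) hold for every
#' seed.
#'
#' @param spec A [phantom_spec()].
#' @param components A [component_set()] containing the four default
#'   components.
#' @param acq An [acquisition_model()].
#' @param noise Poisson-sample the stacks? (default TRUE)
#' @return A list with elements `stacks` (list of [decay_stack()], one per
#'   depth), `truth` (list of row x col x 4 fraction arrays with component
#'   names), `labels` (depth or time-point labels), and `spec`.
#' @export
make_phantom <- function(spec, components = default_components(acq),
                         acq = acquisition_model(), noise = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(components, "component_set"))
  need <- c("free_nadh", "bound_nadh", "keratin", "melanin")
  if (!all(need %in% components$name)) {
    stop("components must contain the four defaults: ",
         paste(need, collapse = ", "))
  }
  shape <- spec$shape
  J <- length(spec$depths)
  withr::with_seed(spec$seed, {
    S_ker <- smooth_field(shape)
    S_mel <- smooth_field(shape)
    folds <- curvilinear_mask(shape, n_curves = 3L,
                              width = max(1, round(shape[1] / 48)))
    disks <- disk_mask(shape, n_disks = max(3L, round(prod(shape) / 2500)))
    hairs <- curvilinear_mask(shape, n_curves = 2L,
                              width = max(2, round(shape[1] / 32)))
    truth <- vector("list", J)
    labels <- character(J)
    for (j in seq_len(J)) {
      dfrac <- if (J > 1L) (j - 1) / (J - 1) else 0
      fr <- switch(spec$preset,
        depth_series_typeV = ,
        depth_series_typeIII = ,
        depth_series_vitiligo = {
          mel_base <- switch(spec$preset,
            depth_series_typeV = 0.03 + 0.32 * dfrac,
            depth_series_typeIII = 0.02 + 0.16 * dfrac,
            depth_series_vitiligo = 0.01)
          rho <- switch(spec$preset,
            depth_series_vitiligo = 0.50,
            0.60 - 0.25 * dfrac)
          ker <- (0.65 - 0.50 * dfrac) * (0.8 + 0.4 * S_ker)
          mel <- mel_base * (0.8 + 0.4 * S_mel)
          ker[folds] <- 0.85
          mel[folds] <- pmin(mel[folds], if (spec$preset ==
            "depth_series_vitiligo") 0.012 else 0.05)
          compose_fractions(ker, mel, rho)
        },
        sk_horn_cysts = {
          ker <- 0.18 * (0.8 + 0.4 * S_ker)
          mel <- 0.40 * (0.8 + 0.4 * S_mel)
          ker[disks] <- 0.85
          mel[disks] <- 0.05
          compose_fractions(ker, mel, 0.5)
        },
        exvivo_pair = {
          ker <- 0.25 * (0.8 + 0.4 * S_ker)
          mel <- 0.08 * (0.8 + 0.4 * S_mel)
          ker[hairs] <- 0.90
          mel[hairs] <- 0.02
          compose_fractions(ker, mel, if (j == 1L) 0.55 else 0.38)
        },
        stratum_corneum = {
          ker <- 0.80 * (0.9 + 0.2 * S_ker)
          ker[folds] <- 0.95
          mel <- matrix(0.02, shape[1], shape[2])
          compose_fractions(ker, mel, 0.5)
        }
      )
      truth[[j]] <- array(fr, c(shape, 4L),
                          dimnames = list(NULL, NULL, colnames(fr)))
      labels[j] <- if (spec$preset == "exvivo_pair") {
        c("0h", "6h")[j]
      } else {
        sprintf("z=%g", spec$depths[j])
      }
    }
    # component decay profiles (distorted), in truth column order
    ord <- match(dimnames(truth[[1]])[[3]], components$name)
    P <- t(vapply(components$tau[ord],
                  function(tv) distorted_profile(tv, acq),
                  numeric(acq$n_bins)))
    stacks <- vector("list", J)
    for (j in seq_len(J)) {
      Fm <- matrix(truth[[j]], prod(shape), 4L)
      E <- (Fm %*% P) * spec$mean_photons
      if (noise) {
        cnt <- matrix(stats::rpois(length(E), pmax(E, 0)),
                      nrow(E), ncol(E))
      } else {
        cnt <- E
      }
      stacks[[j]] <- decay_stack(array(cnt, c(shape, acq$n_bins)), acq,
                                 z = spec$depths[j])
    }
    list(stacks = stacks, truth = truth, labels = labels, spec = spec)
  })
}
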