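#' Per-bin emission probabilities of a periodic mono-exponential decay
#'
#' Computes the probability that a photon from a single-exponential emitter
#' with lifetime `tau`, excited by a pulse train of period `acq$period`, is
#' recorded in each of the `acq$n_bins` time bins. The continuous density is
#' the periodically wrapped exponential \eqn{e^{-t/\tau}/(\tau(1-e^{-T/\tau}))}
#' on \eqn{[0, T)}, integrated over each bin. `tau = 0` is the delta limit
#' (all mass at t = 0). When `acq$irf_sigma > 0` the density is first
#' convolved in continuous time with a (wrapped) Gaussian of that width and
#' then integrated over bins; this is evaluated through the exact Fourier
#' series of the convolved periodic density, so arbitrarily long lifetimes
#' are handled without underflow.
#'
#' @param tau Fluorescence lifetime in ns (>= 0).
#' @param acq An [acquisition_model()].
#' @return Numeric vector of length `acq$n_bins` summing to 1.
#' @export
#' @examples
#' p <- decay_model(2.5, acquisition_model(irf_sigma = 0))
#' sum(p)  # 1
decay_model <- function(tau, acq = acquisition_model()) {
  stopifnot(inherits(acq, "acquisition_model"))
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    stop("tau must be a single non-negative number (ns)")
  }
  n <- acq$n_bins
  Tp <- acq$period
  dt <- acq$bin_width
  if (acq$irf_sigma <= 0) {
    if (tau == 0) return(c(1, rep(0, n - 1L)))
    # integral of wrapped exponential over bin k: expm1-safe for huge tau
    k <- 0:(n - 1L)
    p <- exp(-k * dt / tau) * (-expm1(-dt / tau)) / (-expm1(-Tp / tau))
    return(p / sum(p))
  }
  # Fourier-series route: periodic exponential (or delta) convolved with a
  # Gaussian has coefficients F_h = e^{-(h w sigma)^2/2} / (1 - i h w tau);
  # the integral over bin k multiplies by sinc(pi h / n) and a phase ramp.
  w <- 2 * pi / Tp
  sig <- acq$irf_sigma
  # truncate where the Gaussian factor is below ~1e-18
  H <- max(1L, ceiling(9 / (w * sig)))
  h <- seq_len(H)
  Fh <- exp(-(h * w * sig)^2 / 2) / complex(real = 1, imaginary = h * w * tau)
  sinc <- sin(pi * h / n) / (pi * h / n)
  k <- 0:(n - 1L)
  # p_k = 1/n * [1 + 2 Re sum_h Fh sinc_h e^{2 pi i h (k + 0.5)/n}]
  phase <- outer(k + 0.5, h, function(kk, hh) 2 * pi * hh * kk / n)
  re <- cos(phase) %*% (Re(Fh) * sinc) - sin(phase) %*% (Im(Fh) * sinc)
  p <- (1 + 2 * as.vector(re)) / n
  p / sum(p)
}

#' Construct a decay stack
#'
#' A decay stack is the raw object of the analysis: per-pixel photon counts
#' over the time bins of one laser period, with acquisition metadata.
#'
#' @param counts 3-D numeric array indexed (row, col, time_bin).
#' @param acquisition An [acquisition_model()]; third array dimension must
#'   equal `acquisition$n_bins`.
#' @param z Optional depth in micrometres.
#' @param channel_label Detection-channel label (default `"A0"`, the
#'   blue-shifted channel used to minimise the FAD contribution).
#' @return An object of class `decay_stack`.
#' @export
decay_stack <- function(counts, acquisition, z = NA_real_,
                        channel_label = "A0") {
  stopifnot(inherits(acquisition, "acquisition_model"))
  if (length(dim(counts)) != 3L) {
    stop("counts must be a 3-D array (row, col, time_bin)")
  }
  if (dim(counts)[3] != acquisition$n_bins) {
    stop(sprintf("counts has %d time bins but acquisition declares %d",
                 dim(counts)[3], acquisition$n_bins))
  }
  structure(list(
    counts = counts,
    acquisition = acquisition,
    z = z,
    channel_label = channel_label
  ), class = "decay_stack")
}

#' @export
print.decay_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<decay_stack> %d x %d pixels, %d bins, channel %s%s\n",
              d[1], d[2], d[3], x$channel_label,
              if (is.na(x$z)) "" else sprintf(", z = %g um", x$z)))
  cat(sprintf("  total photons: %.6g\n", sum(x$counts)))
  invisible(x)
}

# DFT-domain multipliers implementing the instrument distortion:
# every non-DC harmonic attenuated by mod_loss, harmonic h phase-shifted so
# that the measured phasor is multiplied by mod_loss * exp(-i h phase_offset)
# (hence the calibration recovers phi_1 = +phase_offset, m_1 = 1/mod_loss).
distortion_dft_factors <- function(acq) {
  n <- acq$n_bins
  a <- acq$mod_loss
  phi <- acq$phase_offset
  f <- complex(real = rep(1, n))
  half <- n %/% 2L
  hs <- seq_len(half - 1L)
  # phasor P_h = e^{i h pi / n} conj(C_h)/N  =>  multiply C_h by a e^{+i h phi}
  f[1L + hs] <- a * exp(1i * hs * phi)
  f[1L + (n - hs)] <- Conj(f[1L + hs])
  # Nyquist bin must stay real
  f[1L + half] <- a * cos(half * phi)
  f
}

# apply distortion to a (pixels x n_bins) matrix of expected counts
distort_matrix <- function(X, acq) {
  f <- distortion_dft_factors(acq)
  # mvfft works on columns; transpose so each column is one pixel's decay
  C <- stats::mvfft(t(X))
  C <- C * f
  t(Re(stats::mvfft(C, inverse = TRUE))) / acq$n_bins
}

#' Apply instrument distortion to a decay stack
#'
#' Imposes the minimal distortion family that session calibration against a
#' reference dye corrects: a circular phase shift of
#' `phase_offset/(2*pi) * period` and a harmonic-domain attenuation that
#' multiplies every harmonic's modulation by `mod_loss`. The parameters are
#' read from `stack$acquisition`. Identity parameters return the input
#' unchanged; the per-pixel total expected photons are conserved exactly
#' (the DC term is untouched).
#'
#' @param stack A [decay_stack()] of (noiseless) expected counts.
#' @return A `decay_stack` with distorted expectations.
#' @export
apply_instrument_distortion <- function(stack) {
  stopifnot(inherits(stack, "decay_stack"))
  acq <- stack$acquisition
  if (!(acq$mod_loss > 0 && acq$mod_loss <= 1)) {
    stop("mod_loss must be in (0, 1]")
  }
  if (acq$phase_offset == 0 && acq$mod_loss == 1) {
    return(stack)
  }
  d <- dim(stack$counts)
  X <- matrix(stack$counts, d[1] * d[2], d[3])
  Xd <- distort_matrix(X, acq)
  stack$counts <- array(Xd, d)
  stack
}

# distorted expected decay profile (length n_bins, sums to 1) for one lifetime
distorted_profile <- function(tau, acq) {
  p <- decay_model(tau, acq)
  if (acq$phase_offset == 0 && acq$mod_loss == 1) return(p)
  as.vector(distort_matrix(matrix(p, 1L), acq))
}

#' Simulate a mono-exponential decay stack (calibration standard)
#'
#' Every pixel shares the expected decay `mean_photons * decay_model(tau)`,
#' distorted by the instrument parameters in `acq`. With `noise = TRUE`,
#' per-(pixel, bin) counts are drawn independently from Poisson distributions
#' with those means (negative ringing of near-delta expectations is clamped
#' at zero for sampling); otherwise the real-valued expectations are
#' returned. This is exactly the shape of a reference-dye calibration stack
#' such as Coumarin 6 (2.5 ns) or dimethyl-POPOP (1.45 ns) in ethanol.
#'
#' @param tau Lifetime in ns.
#' @param shape Integer vector (rows, cols).
#' @param mean_photons Expected photons per pixel (> 0).
#' @param acq An [acquisition_model()].
#' @param noise Draw Poisson counting noise?
#' @param seed RNG seed used when `noise = TRUE` (the global RNG state is
#'   left untouched).
#' @param z,channel_label Passed to [decay_stack()].
#' @return A [decay_stack()].
#' @export
make_monoexponential_stack <- function(tau, shape = c(64L, 64L),
                                       mean_photons = 225,
                                       acq = acquisition_model(),
                                       noise = FALSE, seed = 1L,
                                       z = NA_real_, channel_label = "A0") {
  stopifnot(length(shape) == 2L, all(shape >= 1), mean_photons > 0)
  shape <- as.integer(shape)
  prof <- mean_photons * distorted_profile(tau, acq)
  npix <- shape[1] * shape[2]
  counts <- matrix(prof, nrow = npix, ncol = acq$n_bins, byrow = TRUE)
  if (noise) {
    counts <- withr::with_seed(as.integer(seed), {
      matrix(stats::rpois(length(counts), pmax(counts, 0)),
             nrow = npix, ncol = acq$n_bins)
    })
  }
  decay_stack(array(counts, c(shape, acq$n_bins)), acq,
              z = z, channel_label = channel_label)
}
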