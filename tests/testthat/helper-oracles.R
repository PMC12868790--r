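# shared fixtures and independent oracles

acq_ideal <- function(...) acquisition_model(irf_sigma = 0, ...)

# brute-force oracle for the periodic mono-exponential bin probabilities:
# sum e^{-(t + kT)/tau} over k = 0..50, midpoint-sampled at n_pts per bin
brute_decay_bins <- function(tau, acq, n_pts = 1e4, k_max = 50) {
  Tp <- acq$period
  n <- acq$n_bins
  tt <- seq(0, Tp, length.out = n * n_pts + 1)
  mid <- (tt[-1] + tt[-length(tt)]) / 2
  dens <- rep(0, length(mid))
  for (k in 0:k_max) dens <- dens + exp(-(mid + k * Tp) / tau)
  p <- tapply(dens, rep(seq_len(n), each = n_pts), sum)
  unname(p / sum(p))
}

# EMG-sum oracle for the Gaussian-IRF decay model (wrapped sum of
# exponentially-modified-Gaussian bin integrals)
emg_decay_bins <- function(tau, acq) {
  n <- acq$n_bins
  Tp <- acq$period
  sig <- acq$irf_sigma
  edges <- (0:n) * acq$bin_width
  cdf <- function(x) {
    u <- x / sig
    stats::pnorm(u) - exp(sig^2 / (2 * tau^2) - x / tau +
                            stats::pnorm(u - sig / tau, log.p = TRUE))
  }
  tot <- numeric(n)
  if (tau == 0) {
    for (m in -4:4) {
      tot <- tot + (stats::pnorm(edges[-1] - m * Tp, 0, sig) -
                      stats::pnorm(edges[-(n + 1)] - m * Tp, 0, sig))
    }
  } else {
    for (m in -4:80) {
      tot <- tot + (cdf(edges[-1] + m * Tp) - cdf(edges[-(n + 1)] + m * Tp))
    }
  }
  tot / sum(tot)
}

# discrete phasor of a single pooled decay vector (direct summation)
discrete_phasor <- function(p, acq, n = 1) {
  tk <- (seq_along(p) - 0.5) * acq$bin_width
  w <- n * 2 * pi / acq$period
  complex(real = sum(p * cos(w * tk)), imaginary = sum(p * sin(w * tk))) /
    sum(p)
}

# calibrated phasor field of a noiseless monoexponential stack, calibrating
# on a reference of lifetime ref_tau simulated under the same acquisition
calibrated_mono_field <- function(tau, acq, ref_tau = 2.5, shape = c(8, 8)) {
  ref <- make_monoexponential_stack(ref_tau, shape, 200, acq)
  cal <- compute_calibration(ref, ref_tau)
  st <- make_monoexponential_stack(tau, shape, 200, acq)
  apply_calibration(phasor_transform(st), cal)
}
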