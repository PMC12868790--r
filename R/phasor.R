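#' Per-pixel harmonic phasor transform
#'
#' Maps each pixel's decay to phasor coordinates at the requested harmonics
#' of the laser repetition rate. For counts \eqn{c_k} in bins with centers
#' \eqn{t_k = (k + 1/2)\Delta t}:
#' \deqn{g_n = \sum_k c_k \cos(n\omega t_k) / \sum_k c_k, \quad
#'       s_n = \sum_k c_k \sin(n\omega t_k) / \sum_k c_k}
#' with \eqn{\omega = 2\pi/T}. The per-pixel intensity is the exact time sum
#' of the stack; pixels with zero photons have undefined phasors (stored as
#' `NA`, never silently zero).
#'
#' @param stack A [decay_stack()].
#' @param harmonics Integer harmonics, each in `1..(n_bins/2 - 1)`.
#' @return An object of class `phasor_field` with fields `g`, `s`
#'   (row x col x harmonic arrays), `intensity`, `harmonics`, `calibrated`
#'   (FALSE), `acquisition`.
#' @export
phasor_transform <- function(stack, harmonics = c(1L, 2L)) {
  stopifnot(inherits(stack, "decay_stack"))
  acq <- stack$acquisition
  harmonics <- as.integer(harmonics)
  nyq <- acq$n_bins %/% 2L
  if (any(harmonics < 1L) || any(harmonics > nyq - 1L)) {
    stop(sprintf("harmonics must lie in 1..%d for %d time bins",
                 nyq - 1L, acq$n_bins))
  }
  d <- dim(stack$counts)
  X <- matrix(stack$counts, d[1] * d[2], d[3])
  tk <- bin_centers(acq)
  N <- rowSums(X)
  H <- length(harmonics)
  g <- array(NA_real_, c(d[1], d[2], H))
  s <- array(NA_real_, c(d[1], d[2], H))
  ok <- N != 0
  for (j in seq_len(H)) {
    wt <- omega_n(acq, harmonics[j]) * tk
    gj <- as.vector(X %*% cos(wt))
    sj <- as.vector(X %*% sin(wt))
    gj[ok] <- gj[ok] / N[ok]; gj[!ok] <- NA_real_
    sj[ok] <- sj[ok] / N[ok]; sj[!ok] <- NA_real_
    g[, , j] <- gj
    s[, , j] <- sj
  }
  phasor_field(g, s, matrix(N, d[1], d[2]), harmonics,
               calibrated = FALSE, acquisition = acq)
}

#' Construct a phasor field
#'
#' @param g,s Row x col x harmonic arrays of phasor coordinates (a matrix is
#'   promoted to a single-harmonic array).
#' @param intensity Row x col matrix of per-pixel photon totals.
#' @param harmonics Integer vector of harmonic numbers, one per slice.
#' @param calibrated Has the session calibration been applied?
#' @param acquisition The [acquisition_model()] of the source stack.
#' @return An object of class `phasor_field`.
#' @export
phasor_field <- function(g, s, intensity, harmonics,
                         calibrated = FALSE, acquisition = NULL) {
  if (length(dim(g)) == 2L) g <- array(g, c(dim(g), 1L))
  if (length(dim(s)) == 2L) s <- array(s, c(dim(s), 1L))
  harmonics <- as.integer(harmonics)
  stopifnot(dim(g)[3] == length(harmonics), all(dim(g) == dim(s)),
            all(dim(intensity) == dim(g)[1:2]))
  structure(list(
    g = g, s = s, intensity = intensity,
    harmonics = harmonics, calibrated = calibrated,
    acquisition = acquisition
  ), class = "phasor_field")
}

#' @export
print.phasor_field <- function(x, ...) {
  d <- dim(x$g)
  cat(sprintf("<phasor_field> %d x %d pixels, harmonics {%s}, %s\n",
              d[1], d[2], paste(x$harmonics, collapse = ", "),
              if (x$calibrated) "calibrated" else "uncalibrated"))
  cat(sprintf("  defined pixels: %d / %d\n",
              sum(x$intensity != 0), length(x$intensity)))
  invisible(x)
}

# slice index for harmonic n, with a helpful error
harmonic_slice <- function(field, n) {
  j <- match(as.integer(n), field$harmonics)
  if (is.na(j)) {
    stop(sprintf(
      "harmonic %d not present (have {%s}); re-run phasor_transform with it",
      n, paste(field$harmonics, collapse = ", ")))
  }
  j
}

#' Closed-form phasor of a mono-exponential decay
#'
#' For lifetime `tau` at harmonic `n`,
#' \eqn{g = 1/(1 + (n\omega\tau)^2)}, \eqn{s = n\omega\tau/(1+(n\omega\tau)^2)};
#' the point lies exactly on the universal circle \eqn{g^2 + s^2 = g}.
#'
#' @param tau Lifetime in ns (>= 0); may be a vector.
#' @param n Harmonic number.
#' @param acq An [acquisition_model()].
#' @return A list with numeric fields `g` and `s` (same length as `tau`).
#' @export
#' @examples
#' analytic_phasor(2.5, 1, acquisition_model())  # g ~ 0.388, s ~ 0.487
analytic_phasor <- function(tau, n = 1L, acq = acquisition_model()) {
  if (any(tau < 0)) stop("tau must be >= 0")
  wt <- omega_n(acq, n) * tau
  list(g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

#' Session calibration from a reference-dye stack
#'
#' Pools all photons of the reference stack into a single decay, computes its
#' uncalibrated phasor at each requested harmonic, and returns the
#' per-harmonic modulation correction \eqn{m_n} and phase correction
#' \eqn{\phi_n} that map the measured reference phasor onto the closed-form
#' phasor of the reference's nominal lifetime. Both harmonics are calibrated
#' from the same reference, mirroring the one-dye-per-session workflow; the
#' correction absorbs the instrument phase shift and modulation loss together
#' with any residual discrete-binning bias.
#'
#' @param reference A [decay_stack()] of the calibration standard.
#' @param nominal_tau Known mono-exponential lifetime of the reference (ns),
#'   e.g. 2.5 for Coumarin 6 or 1.45 for dimethyl-POPOP in ethanol.
#' @param harmonics Harmonics to calibrate.
#' @param reference_name Label stored with the factors.
#' @return An object of class `calibration_factors`: per-harmonic `m` (> 0)
#'   and `phi` (radians in (-pi, pi]), plus `reference_name`, `reference_tau`,
#'   `harmonics`.
#' @export
compute_calibration <- function(reference, nominal_tau,
                                harmonics = c(1L, 2L),
                                reference_name = "reference") {
  stopifnot(inherits(reference, "decay_stack"))
  pooled <- apply(reference$counts, 3, sum)
  if (sum(pooled) <= 0) stop("reference stack contains no photons")
  acq <- reference$acquisition
  tk <- bin_centers(acq)
  harmonics <- as.integer(harmonics)
  m <- numeric(length(harmonics))
  phi <- numeric(length(harmonics))
  for (j in seq_along(harmonics)) {
    wt <- omega_n(acq, harmonics[j]) * tk
    meas <- complex(real = sum(pooled * cos(wt)),
                    imaginary = sum(pooled * sin(wt))) / sum(pooled)
    if (Mod(meas) < 1e-12) stop("reference unmodulated")
    a <- analytic_phasor(nominal_tau, harmonics[j], acq)
    corr <- complex(real = a$g, imaginary = a$s) / meas
    m[j] <- Mod(corr)
    phi[j] <- Arg(corr)
  }
  structure(list(
    m = m, phi = phi, harmonics = harmonics,
    reference_name = reference_name, reference_tau = nominal_tau
  ), class = "calibration_factors")
}

#' @export
print.calibration_factors <- function(x, ...) {
  cat(sprintf("<calibration_factors> reference %s (%g ns)\n",
              x$reference_name, x$reference_tau))
  for (j in seq_along(x$harmonics)) {
    cat(sprintf("  n = %d: m = %.6f, phi = %.6f rad\n",
                x$harmonics[j], x$m[j], x$phi[j]))
  }
  invisible(x)
}

#' Apply calibration factors to a phasor field
#'
#' Treats each pixel's `(g, s)` at harmonic n as the complex number
#' `g + i s` and multiplies by `m_n * exp(i phi_n)`. Intensity is unchanged;
#' the calibrated flag is set. Calibrating twice is an error.
#'
#' @param field An uncalibrated [phasor_field()].
#' @param cal A [compute_calibration()] result covering the field's harmonics.
#' @return The calibrated `phasor_field`.
#' @export
apply_calibration <- function(field, cal) {
  stopifnot(inherits(field, "phasor_field"),
            inherits(cal, "calibration_factors"))
  if (field$calibrated) stop("field is already calibrated")
  for (j in seq_along(field$harmonics)) {
    cj <- match(field$harmonics[j], cal$harmonics)
    if (is.na(cj)) {
      stop(sprintf("calibration lacks harmonic %d", field$harmonics[j]))
    }
    rot <- cal$m[cj] * exp(1i * cal$phi[cj])
    z <- complex(real = field$g[, , j], imaginary = field$s[, , j]) * rot
    field$g[, , j] <- array(Re(z), dim(field$g)[1:2])
    field$s[, , j] <- array(Im(z), dim(field$s)[1:2])
  }
  field$calibrated <- TRUE
  field$calibration <- cal
  field
}

#' Per-pixel phase lifetime
#'
#' Projects each calibrated phasor onto the universal circle along its phase
#' angle: \eqn{\tau_\phi = \tan(\mathrm{atan2}(s_n, g_n)) / (n\omega)}, the
#' lifetime of the single-exponential species with the same phase shift as
#' the measurement. Pixels with `g <= 0` (phase beyond the quarter turn,
#' where the projection is not meaningful) or undefined phasors are returned
#' as `NA`.
#'
#' @param field A calibrated [phasor_field()].
#' @param n Harmonic to use (default 1).
#' @return Matrix of lifetimes in ns, `NA` where invalid.
#' @export
phase_lifetime <- function(field, n = 1L) {
  stopifnot(inherits(field, "phasor_field"))
  if (!field$calibrated) stop("field must be calibrated before phase_lifetime")
  j <- harmonic_slice(field, n)
  d <- dim(field$g)[1:2]
  g <- array(field$g[, , j], d)
  s <- array(field$s[, , j], d)
  tau <- s / (g * omega_n(field$acquisition, n))
  tau[!is.na(g) & g <= 0] <- NA_real_
  tau
}
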