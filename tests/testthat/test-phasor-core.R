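test_that("phasor transform: single-bin, DC-only and oracle agreement", {
  acq <- acq_ideal()
  # all photons in bin 0 -> unit-circle point at angle omega * t0
  delta <- decay_stack(array(c(10, rep(0, 31)), c(1, 1, 32)), acq)
  f <- phasor_transform(delta, 1:2)
  t0 <- acq$bin_width / 2
  w <- 2 * pi / acq$period
  expect_equal(f$g[1, 1, 1], cos(w * t0), tolerance = 1e-12)
  expect_equal(f$s[1, 1, 1], sin(w * t0), tolerance = 1e-12)
  expect_equal(f$g[1, 1, 1]^2 + f$s[1, 1, 1]^2, 1, tolerance = 1e-12)

  # uniform counts are DC-only: phasor at the origin for n in {1, 2}
  flat <- decay_stack(array(5, c(2, 2, 32)), acq)
  ff <- phasor_transform(flat, 1:2)
  expect_equal(max(abs(ff$g)), 0, tolerance = 1e-12)
  expect_equal(max(abs(ff$s)), 0, tolerance = 1e-12)

  # noiseless 2.5 ns stack equals the direct-summation discrete oracle
  st <- make_monoexponential_stack(2.5, c(3, 3), 100, acq, noise = FALSE)
  fu <- phasor_transform(st, 1:2)
  for (n in 1:2) {
    z <- discrete_phasor(decay_model(2.5, acq), acq, n)
    expect_equal(fu$g[2, 2, n], Re(z), tolerance = 1e-12)
    expect_equal(fu$s[2, 2, n], Im(z), tolerance = 1e-12)
  }

  # intensity equals the time sum exactly, zero-photon pixels undefined
  counts <- array(rpois(4 * 4 * 32, 3), c(4, 4, 32))
  counts[2, 3, ] <- 0
  fz <- phasor_transform(decay_stack(counts, acq))
  expect_identical(fz$intensity, apply(counts, c(1, 2), sum))
  expect_true(is.na(fz$g[2, 3, 1]))
  expect_false(anyNA(fz$g[, , 1][fz$intensity > 0]))

  expect_error(phasor_transform(st, 16), "harmonics")
  expect_error(phasor_transform(st, 0), "harmonics")
})

test_that("analytic phasor sits on the universal circle with known values", {
  acq <- acquisition_model()
  expect_equal(analytic_phasor(0, 1, acq), list(g = 1, s = 0))
  far <- analytic_phasor(1e12, 1, acq)
  expect_equal(far$g, 0, tolerance = 1e-12)
  expect_equal(far$s, 0, tolerance = 1e-10)
  p <- analytic_phasor(2.5, 1, acq)
  expect_equal(p$g, 0.38773, tolerance = 1e-4)
  expect_equal(p$s, 0.48723, tolerance = 1e-4)
  # numerical Fourier-integral cross-check
  w <- 2 * pi / acq$period
  tt <- seq(0, 4000 * 2.5, length.out = 4e6)
  dens <- exp(-tt / 2.5)
  gnum <- sum(dens * cos(w * tt)) / sum(dens)
  snum <- sum(dens * sin(w * tt)) / sum(dens)
  expect_equal(p$g, gnum, tolerance = 2e-3)
  expect_equal(p$s, snum, tolerance = 2e-3)
  # exactly on g^2 + s^2 = g for a sweep of lifetimes and both harmonics
  for (n in 1:2) {
    ap <- analytic_phasor(seq(0, 20, by = 0.37), n, acq)
    expect_equal(ap$g^2 + ap$s^2, ap$g, tolerance = 1e-14)
  }
  expect_error(analytic_phasor(-0.1), ">= 0")
})

test_that("calibration: identity factors against the discrete oracle", {
  acq <- acq_ideal()
  ref <- make_monoexponential_stack(2.5, c(4, 4), 100, acq, noise = FALSE)
  cal <- compute_calibration(ref, 2.5)
  # factors map the pooled discrete phasor exactly onto the closed form
  for (j in 1:2) {
    meas <- discrete_phasor(decay_model(2.5, acq), acq, j)
    a <- analytic_phasor(2.5, j, acq)
    corr <- complex(real = a$g, imaginary = a$s) / meas
    expect_equal(cal$m[j], Mod(corr), tolerance = 1e-12)
    expect_equal(cal$phi[j], Arg(corr), tolerance = 1e-12)
  }
  expect_error(
    compute_calibration(decay_stack(array(0, c(2, 2, 32)), acq), 2.5),
    "no photons")
  expect_error(
    compute_calibration(decay_stack(array(1, c(2, 2, 32)), acq), 2.5),
    "unmodulated")
})

test_that("calibration inverts a known instrument distortion", {
  base <- acquisition_model()
  dist <- acquisition_model(phase_offset = 0.3, mod_loss = 0.8)
  cal0 <- compute_calibration(
    make_monoexponential_stack(2.5, c(4, 4), 100, base), 2.5)
  cal1 <- compute_calibration(
    make_monoexponential_stack(2.5, c(4, 4), 100, dist), 2.5)
  expect_equal(cal1$phi[1] - cal0$phi[1], 0.3, tolerance = 1e-6)
  expect_equal(cal1$m[1] / cal0$m[1], 1 / 0.8, tolerance = 1e-6)
  expect_equal(cal1$phi[2] - cal0$phi[2], 0.6, tolerance = 1e-6)
  expect_equal(cal1$m[2] / cal0$m[2], 1 / 0.8, tolerance = 1e-6)
})

test_that("cross-standard round trip recovers the other dye's lifetime", {
  for (acq in list(acquisition_model(phase_offset = 0.3, mod_loss = 0.8),
                   acq_ideal(phase_offset = 0.3, mod_loss = 0.8))) {
    ref_c6 <- make_monoexponential_stack(2.5, c(8, 8), 225, acq)
    ref_pp <- make_monoexponential_stack(1.45, c(8, 8), 225, acq)
    cal_c6 <- compute_calibration(ref_c6, 2.5, reference_name = "coumarin6")
    cal_pp <- compute_calibration(ref_pp, 1.45, reference_name = "popop")
    tau_pp <- median(phase_lifetime(
      apply_calibration(phasor_transform(ref_pp), cal_c6)))
    tau_c6 <- median(phase_lifetime(
      apply_calibration(phasor_transform(ref_c6), cal_pp)))
    expect_equal(tau_pp, 1.45, tolerance = 0.01)
    expect_equal(tau_c6, 2.5, tolerance = 0.01)
  }
})

test_that("apply_calibration rotates/scales and refuses double work", {
  acq <- acquisition_model()
  f <- phasor_field(matrix(1, 1, 1), matrix(0, 1, 1), matrix(10, 1, 1),
                    1L, acquisition = acq)
  cal <- structure(list(m = 1, phi = pi / 2, harmonics = 1L,
                        reference_name = "synthetic", reference_tau = 1),
                   class = "calibration_factors")
  fc <- apply_calibration(f, cal)
  expect_equal(fc$g[1, 1, 1], 0, tolerance = 1e-12)
  expect_equal(fc$s[1, 1, 1], 1, tolerance = 1e-12)
  expect_identical(fc$intensity, f$intensity)
  expect_true(fc$calibrated)
  expect_error(apply_calibration(fc, cal), "already calibrated")
  id <- structure(list(m = c(1, 1), phi = c(0, 0), harmonics = 1:2,
                       reference_name = "id", reference_tau = 1),
                  class = "calibration_factors")
  g <- array(runif(8), c(2, 2, 2)); s <- array(runif(8), c(2, 2, 2))
  f2 <- phasor_field(g, s, matrix(1, 2, 2), 1:2, acquisition = acq)
  f2c <- apply_calibration(f2, id)
  expect_equal(f2c$g, g)
  expect_equal(f2c$s, s)
})

test_that("calibrated monoexponentials land on the universal circle", {
  # invariant to the distortion used during generation
  for (par in list(c(0, 1), c(0.3, 0.8), c(-0.9, 0.4))) {
    acq <- acquisition_model(phase_offset = par[1], mod_loss = par[2])
    for (tau in c(0.4, 1.1, 3.4)) {
      f <- calibrated_mono_field(tau, acq, ref_tau = 2.5)
      g <- f$g[1, 1, 1]; s <- f$s[1, 1, 1]
      expect_lt(abs(g^2 + s^2 - g), 1e-6)
      a <- analytic_phasor(tau, 1, acq)
      expect_lt(abs(g - a$g) + abs(s - a$s), 1e-6)
    }
  }
})

test_that("calibrated mixture phasors are photon-weighted vertex sums", {
  acq <- acquisition_model(phase_offset = 0.2, mod_loss = 0.9)
  comps <- default_components(acq)
  cal <- compute_calibration(
    make_monoexponential_stack(2.5, c(4, 4), 100, acq), 2.5)
  fr <- c(0.3, 0.25, 0.35, 0.1)
  profiles <- vapply(comps$tau, function(tv) {
    make_monoexponential_stack(tv, c(1, 1), 1, acq)$counts[1, 1, ]
  }, numeric(32))
  mix <- decay_stack(array(200 * as.vector(profiles %*% fr), c(1, 1, 32)),
                     acq)
  fm <- apply_calibration(phasor_transform(mix, 1:2), cal)
  for (n in 1:2) {
    vg <- comps[[sprintf("g%d", n)]]
    vs <- comps[[sprintf("s%d", n)]]
    expect_lt(abs(fm$g[1, 1, n] - sum(fr * vg)), 1e-6)
    expect_lt(abs(fm$s[1, 1, n] - sum(fr * vs)), 1e-6)
  }
})

test_that("phase lifetime: fixed points, pure components, monotonicity", {
  acq <- acquisition_model()
  w <- 2 * pi / acq$period
  mk <- function(g, s) {
    phasor_field(matrix(g, 1, 1), matrix(s, 1, 1), matrix(100, 1, 1), 1L,
                 calibrated = TRUE, acquisition = acq)
  }
  expect_equal(phase_lifetime(mk(1, 0))[1, 1], 0)
  expect_equal(phase_lifetime(mk(0.5, 0.5))[1, 1], 1 / w, tolerance = 1e-9)
  expect_equal(1 / w, 1.98944, tolerance = 1e-5)
  expect_true(is.na(phase_lifetime(mk(-0.1, 0.5))[1, 1]))
  expect_error(phase_lifetime(
    phasor_field(matrix(1, 1, 1), matrix(0, 1, 1), matrix(1, 1, 1), 1L,
                 calibrated = FALSE, acquisition = acq)), "calibrated")

  # pure default components after dye calibration
  dist <- acquisition_model(phase_offset = 0.3, mod_loss = 0.8)
  for (tau in c(0.4, 1.1, 3.4)) {
    f <- calibrated_mono_field(tau, dist, ref_tau = 2.5)
    expect_equal(median(phase_lifetime(f)), tau, tolerance = 0.02)
  }
  fmel <- calibrated_mono_field(0, dist, ref_tau = 2.5)
  expect_equal(median(phase_lifetime(fmel)), 0, tolerance = 0.02)
  expect_lt(abs(fmel$g[1, 1, 1] - 1) + abs(fmel$s[1, 1, 1]), 1e-3)

  # monotone along the universal circle from (1,0) toward (0,0)
  taus <- seq(0, 8, by = 0.25)
  ap <- analytic_phasor(taus, 1, acq)
  tp <- vapply(seq_along(taus), function(i) {
    phase_lifetime(mk(ap$g[i], ap$s[i]))[1, 1]
  }, 0)
  expect_true(all(diff(tp) > 0))
})
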