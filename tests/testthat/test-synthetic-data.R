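test_that("acquisition model derives timing from rate and bin count", {
  acq <- acquisition_model()
  expect_equal(acq$period, 12.5)
  expect_equal(acq$bin_width, 0.390625)
  expect_equal(round(acq$bin_width, 2), 0.39)
  expect_error(acquisition_model(n_bins = 2), "at least 4")
  expect_error(acquisition_model(mod_loss = 0), "mod_loss")
  expect_error(acquisition_model(mod_loss = 1.2), "mod_loss")
  expect_error(acquisition_model(irf_sigma = -1), "irf_sigma")
})

test_that("decay_model: delta, normalization, and error cases", {
  acq <- acq_ideal()
  expect_equal(decay_model(0, acq), c(1, rep(0, 31)))
  for (tau in c(0.1, 1.45, 2.5, 40)) {
    expect_equal(sum(decay_model(tau, acq)), 1, tolerance = 1e-12)
  }
  expect_error(decay_model(-1, acq), "non-negative")
  # series-safe for extreme lifetimes: near-uniform, no NaN/underflow
  p <- decay_model(1e9, acq)
  expect_true(all(is.finite(p)))
  expect_equal(p, rep(1 / 32, 32), tolerance = 1e-6)
  p2 <- decay_model(1e9, acquisition_model())
  expect_true(all(is.finite(p2)))
  expect_equal(p2, rep(1 / 32, 32), tolerance = 1e-6)
})

test_that("decay_model matches the brute-force wrapped-series oracle", {
  acq <- acq_ideal()
  for (tau in c(0.4, 1.1, 1.45, 2.5, 3.4, 12.5)) {
    expect_lt(max(abs(decay_model(tau, acq) - brute_decay_bins(tau, acq))),
              1e-9)
  }
})

test_that("Gaussian-IRF decay model matches the wrapped-EMG oracle", {
  acq <- acquisition_model(irf_sigma = 0.39)
  for (tau in c(0, 0.4, 1.1, 2.5, 3.4, 12.5)) {
    expect_lt(max(abs(decay_model(tau, acq) - emg_decay_bins(tau, acq))),
              1e-9)
  }
  # narrower IRF too
  acq2 <- acquisition_model(irf_sigma = 0.1)
  expect_lt(max(abs(decay_model(2.5, acq2) - emg_decay_bins(2.5, acq2))),
            1e-9)
})

test_that("monoexponential stacks: determinism, seeds, Poisson moments", {
  acq <- acq_ideal()
  st <- make_monoexponential_stack(2.5, c(5, 7), 150, acq, noise = FALSE)
  expected <- 150 * decay_model(2.5, acq)
  for (px in list(c(1, 1), c(3, 5), c(5, 7))) {
    expect_equal(st$counts[px[1], px[2], ], expected)
  }
  s1 <- make_monoexponential_stack(1.45, c(8, 8), 225, acq,
                                   noise = TRUE, seed = 42)
  s2 <- make_monoexponential_stack(1.45, c(8, 8), 225, acq,
                                   noise = TRUE, seed = 42)
  s3 <- make_monoexponential_stack(1.45, c(8, 8), 225, acq,
                                   noise = TRUE, seed = 43)
  expect_identical(s1$counts, s2$counts)
  expect_false(identical(s1$counts, s3$counts))
  expect_true(all(s1$counts >= 0))
  expect_true(all(s1$counts == round(s1$counts)))
  # mean photons/pixel within 3 standard errors of the Poisson expectation
  big <- make_monoexponential_stack(2.5, c(64, 64), 225,
                                    acquisition_model(),
                                    noise = TRUE, seed = 7)
  tot <- apply(big$counts, c(1, 2), sum)
  se <- sqrt(225 / length(tot))
  expect_lt(abs(mean(tot) - 225), 3 * se)
})

test_that("instrument distortion: identity, pure shift, conservation", {
  acq_id <- acq_ideal()
  st <- make_monoexponential_stack(1.1, c(4, 4), 100, acq_id, noise = FALSE)
  expect_identical(apply_instrument_distortion(st)$counts, st$counts)

  # phase_offset pi/16 moves a delta by exactly one bin (circularly)
  acq_sh <- acquisition_model(irf_sigma = 0, phase_offset = pi / 16)
  delta <- decay_stack(array(rep(c(1, rep(0, 31)), each = 4), c(2, 2, 32)),
                       acq_sh)
  shifted <- apply_instrument_distortion(delta)
  expect_equal(which(abs(shifted$counts[1, 1, ]) > 1e-9), 32L)
  expect_equal(shifted$counts[1, 1, 32], 1, tolerance = 1e-12)

  # photon totals conserved for arbitrary distortion (direct summation)
  acq_d <- acquisition_model(irf_sigma = 0.2, phase_offset = 0.7,
                             mod_loss = 0.55)
  # an inhomogeneous stack, distorted directly
  counts <- array(runif(4 * 4 * 32, 0, 50), c(4, 4, 32))
  st3 <- decay_stack(counts, acq_d)
  dst3 <- apply_instrument_distortion(st3)
  expect_equal(apply(dst3$counts, c(1, 2), sum),
               apply(counts, c(1, 2), sum), tolerance = 1e-9)
})

test_that("phantom presets honour their ground-truth contracts", {
  acq <- acquisition_model()
  for (seed in c(1, 7)) {
    vit <- make_phantom(phantom_spec("depth_series_vitiligo",
                                     shape = c(24, 24), seed = seed),
                        acq = acq, noise = FALSE)
    mel_max <- max(vapply(vit$truth,
                          function(tr) max(tr[, , "melanin"]), 0))
    expect_lte(mel_max, 0.02)

    tv <- make_phantom(phantom_spec("depth_series_typeV",
                                    shape = c(24, 24), seed = seed),
                       acq = acq, noise = FALSE)
    mel_means <- vapply(tv$truth, function(tr) mean(tr[, , "melanin"]), 0)
    expect_true(all(diff(mel_means) > 0))
    ker_means <- vapply(tv$truth, function(tr) mean(tr[, , "keratin"]), 0)
    expect_true(all(diff(ker_means) < 0))
    # bound share of NADH decreases with depth
    share <- vapply(tv$truth, function(tr) {
      mean(tr[, , "bound_nadh"] / (tr[, , "bound_nadh"] + tr[, , "free_nadh"]))
    }, 0)
    expect_true(all(diff(share) < 0))

    t3 <- make_phantom(phantom_spec("depth_series_typeIII",
                                    shape = c(24, 24), seed = seed),
                       acq = acq, noise = FALSE)
    mel3 <- vapply(t3$truth, function(tr) mean(tr[, , "melanin"]), 0)
    expect_true(all(mel3 > vapply(vit$truth,
                                  function(tr) mean(tr[, , "melanin"]), 0)))
    expect_lt(mean(mel3), mean(mel_means))
  }
})

test_that("horn-cyst and ex-vivo presets build their geometry", {
  sk <- make_phantom(phantom_spec("sk_horn_cysts", shape = c(64, 64),
                                  seed = 3),
                     noise = FALSE)
  ker <- sk$truth[[1]][, , "keratin"]
  expect_true(any(ker >= 0.8))
  # keratin-rich disks embedded in melanin-rich surround
  mel <- sk$truth[[1]][, , "melanin"]
  expect_gt(mean(mel[ker < 0.5]), 0.25)

  ex <- make_phantom(phantom_spec("exvivo_pair", shape = c(32, 32),
                                  seed = 5),
                     noise = FALSE)
  expect_identical(ex$labels, c("0h", "6h"))
  sh <- vapply(ex$truth, function(tr) {
    mean(tr[, , "bound_nadh"] / (tr[, , "bound_nadh"] + tr[, , "free_nadh"]))
  }, 0)
  expect_gt(sh[1], sh[2])
  # identical composition apart from the bound share
  expect_equal(ex$truth[[1]][, , "keratin"], ex$truth[[2]][, , "keratin"])
  expect_equal(ex$truth[[1]][, , "melanin"], ex$truth[[2]][, , "melanin"])

  expect_error(phantom_spec("unknown_thing"), "valid presets")
})

test_that("phantom ground truth sums to one and matches the mixture model", {
  acq <- acquisition_model(phase_offset = 0.25, mod_loss = 0.85)
  comps <- default_components(acq)
  ph <- make_phantom(phantom_spec("depth_series_typeV", shape = c(12, 12),
                                  seed = 11),
                     comps, acq, noise = FALSE)
  for (tr in ph$truth) {
    expect_equal(unname(apply(tr, c(1, 2), sum)),
                 matrix(1, 12, 12), tolerance = 1e-12)
    expect_true(all(tr >= 0))
  }
  # per-pixel expectation = sum_i f_i * mean_photons * distorted decay model
  profiles <- vapply(c("free_nadh", "bound_nadh", "keratin", "melanin"),
                     function(nm) {
                       tau <- comps$tau[match(nm, comps$name)]
                       st <- make_monoexponential_stack(tau, c(1, 1), 1, acq,
                                                        noise = FALSE)
                       st$counts[1, 1, ]
                     }, numeric(32))
  tr <- ph$truth[[3]]
  st <- ph$stacks[[3]]
  for (px in list(c(1, 1), c(7, 9), c(12, 3))) {
    f <- tr[px[1], px[2], ]
    expected <- 225 * as.vector(profiles %*% f)
    expect_equal(st$counts[px[1], px[2], ], expected, tolerance = 1e-9)
  }
  # seed reproducibility of noisy phantoms
  a <- make_phantom(phantom_spec("sk_horn_cysts", shape = c(16, 16),
                                 seed = 2))
  b <- make_phantom(phantom_spec("sk_horn_cysts", shape = c(16, 16),
                                 seed = 2))
  c <- make_phantom(phantom_spec("sk_horn_cysts", shape = c(16, 16),
                                 seed = 9))
  expect_identical(a$stacks[[1]]$counts, b$stacks[[1]]$counts)
  expect_false(identical(a$stacks[[1]]$counts, c$stacks[[1]]$counts))
})
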