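# epiphasor

Phasor-based lifetime unmixing of epidermal autofluorescence.

Label-free two-photon FLIM of human skin mixes, in every pixel, the photons
of a handful of endogenous fluorophores: keratin in the stratum corneum,
melanin in pigmented keratinocytes, and the free and protein-bound forms of
the metabolic coenzyme NADH. `epiphasor` implements the analysis that takes
a time-resolved photon-count image stack apart into those four components:

- **Phasor transform.** Each pixel's decay over the 32 time bins of one
  80 MHz laser period (bin width 0.39 ns) is mapped to harmonic coordinates
  `g_n = Σ c_k cos(nω t_k)/Σ c_k`, `s_n = Σ c_k sin(nω t_k)/Σ c_k`
  with `ω = 2π/T`, for harmonics n = 1, 2.
- **Calibration.** A reference dye of known mono-exponential lifetime
  (Coumarin 6, 2.5 ns, or dimethyl-POPOP, 1.45 ns, in ethanol), imaged in
  the same session, yields a per-harmonic modulation factor and phase shift
  that place the instrument on the universal circle `g² + s² = g`.
- **Phase lifetime.** `τ_φ = tan(atan2(s, g))/(nω)`, the single-exponential
  lifetime with the same phase as the measured phasor.
- **Four-component unmixing.** With component phasors at both harmonics
  (free NADH 0.4 ns, protein-bound NADH 3.4 ns, keratin 1.1 ns, melanin
  0.0 ns), the 5-row system `[g1; s1; g2; s2; 1] f = [G1; S1; G2; S2; 1]`
  is solved per pixel with `Σ f_i = 1` enforced exactly; fractional
  intensities may legitimately be negative at low SNR.
- **Photon-weighted statistics.** Violin-plot summaries (0.1/0.5/0.9
  percentiles, KDE mode) of per-pixel fractions weighted by photon counts,
  the bound-NADH share of total NADH `f_bound/(f_bound + f_free)`, and OLS
  trends of those statistics against imaging depth.

Because clinical FLIM stacks are not redistributable, the package ships a
first-class synthetic-acquisition module: calibration standards, pure
component fields and epidermal phantoms (skin types III/V, vitiligo,
seborrheic-keratosis horn cysts, an ex-vivo 0 h/6 h metabolic pair) with
known ground-truth composition, Poisson counting noise at ~225
photons/pixel, and an instrument model (phase shift, modulation loss,
Gaussian IRF) that the calibration step must undo.

## Worked example

```r
library(epiphasor)

acq   <- acquisition_model(phase_offset = 0.3, mod_loss = 0.8)
comps <- default_components(acq)

# session calibration on a Coumarin 6 standard
cal <- compute_calibration(
  make_monoexponential_stack(2.5, c(16, 16), 225, acq), 2.5,
  reference_name = "coumarin6")

# a noisy five-depth series of highly pigmented (type V) epidermis
ph <- make_phantom(phantom_spec("depth_series_typeV", shape = c(256, 256),
                                mean_photons = 225, seed = 17),
                   comps, acq)

f  <- apply_calibration(phasor_transform(ph$stacks[[4]], 1:2), cal)  # z = 45 um
f  <- median_filter_phasor(bin_spatial(f, 4L))   # 256x256 -> 64x64, 3x3 median
fr <- unmix(f, comps)
violin_summary(fr, "melanin")
```

```
<weighted_distribution> melanin: p10 0.1426, median 0.2617, p90 0.3103, mode 0.2693 (4096 px, 1.475e+07 photons)
```

The melanin fraction distribution at this deep (para-basal) plane centres
near 0.26 — the ground-truth melanin ramp at that depth — with the
10th-90th percentile spread produced by Poisson noise and the programmed
spatial texture. The same calls drive the numbered scripts under `analysis/`
(calibration standards, depth series with trend fits, horn-cyst scene,
ex-vivo pair), each of which writes its tables under `results/`.

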