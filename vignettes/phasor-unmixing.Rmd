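---
title: "Phasor-based unmixing of epidermal autofluorescence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor-based unmixing of epidermal autofluorescence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiphasor)
```

## The measurement model

A pulsed two-photon microscope excites skin at a repetition rate of
80 MHz; the emitted fluorescence of each pixel is histogrammed into 32 time
bins spanning one 12.5 ns laser period, giving a temporal resolution of
0.390625 ns. A pixel's decay is modelled as a mixture of periodically
wrapped mono-exponential emitters. For lifetime $\tau$ the continuous
density on $[0, T)$ is

$$ f(t) = \frac{e^{-t/\tau}}{\tau\,(1 - e^{-T/\tau})}, $$

and `decay_model()` integrates it over each bin (with an `expm1`-safe form
so arbitrarily long lifetimes neither overflow nor underflow; $\tau = 0$ is
the delta limit used for melanin).

The phasor transform maps each pixel to harmonic coordinates

$$ g_n = \frac{\sum_k c_k \cos(n\omega t_k)}{\sum_k c_k}, \qquad
   s_n = \frac{\sum_k c_k \sin(n\omega t_k)}{\sum_k c_k}, $$

with $\omega = 2\pi/T$ and bin-centre timestamps
$t_k = (k + \tfrac12)\Delta t$ (the symmetric choice, which makes the
single-bin delta example exact). Mono-exponential decays fall on the
universal circle $g^2 + s^2 = g$; the phase lifetime
$\tau_\phi = \tan(\mathrm{atan2}(s, g))/(n\omega)$ projects any phasor onto
that circle along its phase angle. Pixels with zero photons carry an
explicit undefined flag (`NA`) through every downstream map — they are
never silently zeroed.

## Instrument response and why the IRF is continuous

The instrument is modelled by three parameters of `acquisition_model()`:

| parameter | meaning | default |
|---|---|---|
| `phase_offset` | phase shift imposed on every harmonic ($h\,\varphi$ at harmonic $h$) | 0 rad |
| `mod_loss` | modulation factor multiplying every non-DC harmonic | 1 |
| `irf_sigma` | Gaussian instrument-response width | 0.39 ns |

`apply_instrument_distortion()` applies the first two in the harmonic
domain (the DC term is untouched, so expected photon totals are conserved
exactly), and session calibration against a reference dye removes them:
`compute_calibration()` pools the reference stack into one decay and
returns the per-harmonic complex factor $m_n e^{i\phi_n}$ that maps the
measured reference phasor onto the closed-form phasor of its nominal
lifetime. Both harmonics are calibrated from the same dye, mirroring the
one-standard-per-session workflow.

The IRF deserves a design note. A discrete histogram of a *sharp* decay is
aliased: the 32-bin phasor of a binned exponential carries a
lifetime-dependent phase bias (up to $\omega\Delta t/2 \approx 0.098$ rad
for the melanin delta) that a single complex calibration factor cannot
absorb, because the factor is shared by all lifetimes. Convolving the
histogram with any symmetric discrete kernel does not help — a symmetric
kernel has a real transfer function, and calibration absorbs real factors.
What removes the bias is band-limiting *before* binning, which is exactly
what a real detector does. `decay_model()` therefore convolves the periodic
decay with a Gaussian IRF in continuous time (evaluated through the exact
Fourier series of the convolved density) and only then integrates over
bins. With the default `irf_sigma = 0.39` ns — matching the instrument's
stated temporal resolution and the ~0.4 ns rise time of hybrid
photodetectors — residual aliasing at harmonics 1 and 2 is below $10^{-9}$,
so one dye calibrates every lifetime: cross-standard round trips
(calibrate on 2.5 ns, read 1.45 ns, and vice versa) and all four component
lifetimes are recovered to well within 0.01 ns. With `irf_sigma = 0` the
package reproduces the classical binned-histogram behaviour, and the
calibration then absorbs the (small, reference-lifetime-specific) binning
bias; the cross-standard error in that mode is below 0.01 ns for the dye
pair but grows toward short lifetimes.

## Processing in the phasor domain

Following the analysis pipeline order: the phasor raster is spatially
binned (`bin_spatial()`, default factor 4, e.g. 1024×1024 → 256×256) by
summing the underlying Fourier numerators and denominators — a
photon-weighted mean of $(g, s)$, never an unweighted average — so binning
commutes with the transform and photons are conserved exactly. A 3×3 median
filter (`median_filter_phasor()`, one pass by default, reflection edges,
undefined pixels excluded) then reduces phasor spread while leaving the
intensity image bit-identical. Integer-factor block binning is the only
downsampling offered: "binning neighbouring pixels" is well defined only
for integer blocks, so non-divisible factors crop the trailing remainder
with a warning rather than resampling.

Masking is explicit and composable: `threshold_mask()` keeps pixels with at
least `min_photons` (default 30 — conservative for ~225-photon pixels after
4×4 binning, while still exercising the low-SNR path), and
`mask_large_keratin_features()` excludes 8-connected components of high
keratin fraction (defaults: fraction > 0.5, area ≥ 200 px) — the rule used
to remove hairs before NADH statistics. Both thresholds are configuration
keys, since no principled universal value exists; masks AND together and
never mutate the fields they select from.

## Unmixing

The component set (free NADH 0.4 ns, protein-bound NADH 3.4 ns, keratin
1.1 ns, melanin 0.0 ns) is converted to phasor coordinates at harmonics 1
and 2, giving the 5×4 design matrix with rows $g_1, s_1, g_2, s_2, 1$.
Per pixel, `unmix()` enforces the normalization row exactly and solves the
four phasor equations by least squares within the affine subspace
$\sum_i f_i = 1$ (parametrised as $f = c + Zu$ with $Z$ a basis of the
sum-zero subspace). Two points drove this choice over ordinary least
squares on all five equations:

- on noiseless (consistent) data the two solvers coincide, so nothing is
  lost;
- on noisy data the exact-sum variant reproduces the diagnostic behaviour
  of the field's tools: a phasor outside the component tetragon yields
  negative fractions with the sum still exactly 1. A non-negativity-
  constrained solver would hide precisely the low-SNR signature that the
  distributions are meant to expose.

Fractions are photon fractions in the detection channel as measured; no
quantum-yield or spectral-brightness correction is applied (concentration
estimation is out of scope). Melanin's $\tau = 0$ puts its vertex exactly
at $(1, 0)$ at both harmonics.

## Photon-weighted statistics

`weighted_percentile()` is the inverse of the weighted empirical CDF: the
smallest value whose cumulative normalized weight reaches $q$, averaging
the two adjacent order statistics when $q$ lands exactly on a
cumulative-weight point. With uniform weights this equals
`quantile(..., type = 2)`. (Full linear interpolation between cumulative
points was rejected: it returns 1.5 for the median of $\{1,2,3\}$, which is
not what any practitioner expects of a percentile.) `weighted_mode()` is
the argmax of a weighted Gaussian KDE on a 512-point grid with Silverman
bandwidth scaled to the weighted standard deviation and the Kish effective
sample size — a mode from a histogram would be bin-origin dependent.
`violin_summary()` retains negative fractions by default (they are
diagnostic; clipping is available but off), and `depth_trend()` fits
unweighted OLS through the per-depth statistics, matching how regression
lines through percentiles and modes are drawn in depth-series analyses.
Both percentile and mode trends are available for every component; the
analysis scripts report percentile trends for keratin/melanin and mode
trends for the bound-NADH ratio.

## The synthetic module: what it emulates, and what it does not

The generator reproduces the acquisition conditions of the study — 80 MHz,
32 bins, ~200–250 (default 225) photons per pixel, per-(pixel, bin)
independent Poisson noise, instrument phase/modulation distortion — and the
compositional structure of the imaged scenarios:

- **Type V / III depth series** (five planes, nominal 0–60 µm): keratin
  ramps 0.65 → 0.15 while melanin ramps 0.03 → 0.35 (type V) or
  0.02 → 0.18 (type III); the bound share of NADH falls 0.60 → 0.35,
  emulating the more glycolytic basal layers. Curvilinear high-keratin
  folds (fraction 0.85) give the deep keratin distribution its second mode.
- **Vitiligo**: melanin ≤ 0.02 everywhere and a depth-constant bound share
  of 0.50.
- **Horn cysts**: keratin-0.85 disks in a melanin-rich (0.40) surround.
- **Ex-vivo pair**: identical composition at "0 h" and "6 h" except the
  bound share drops 0.55 → 0.38; hair-like keratin streaks are present so
  the large-feature mask has work to do.

Smooth multiplicative textures (seeded random-phase sinusoids) are shared
across depths, so per-depth means follow the programmed ramps exactly and
the monotonicity contracts hold for every seed. Exact textures are free
parameters of the generator; only the contracts are guaranteed. The ramp
endpoints and the ex-vivo share drop are the package's own choices of
realistic magnitudes — the study reports trends and shifts, not calibrated
fraction values per depth.

What the phantoms deliberately do **not** model: depth-dependent optical
attenuation and PSF degradation, FAD and dermal fluorophores (collagen,
elastin), spectral (two-channel) detection, detector afterpulsing or dark
counts, and multi-exponential keratin kinetics (keratin is treated as a
1.1 ns single exponential). Passing tests therefore demonstrate that the
*analysis* is correct and well conditioned under realistic counting noise;
they do not certify performance against tissue effects the generator
omits. Phantom depths are nominal labels, not an optical model.

## Numerical choices and degenerate inputs

- Expected counts are exact in the noiseless path; Poisson sampling clamps
  the (rarely, slightly negative) ringing of fractionally phase-shifted
  near-delta decays at zero.
- Calibration errors out on an unmodulated reference (phasor at the
  origin); `phase_lifetime()` returns `NA` for $g \le 0$ rather than
  extrapolating beyond the quarter turn.
- The unmixing normal equations involve a 4×3 system only; the design
  matrix is rank-checked and duplicate-lifetime components are reported by
  name.
- `weighted_mode()` returns the common value with a message for degenerate
  (all-equal) samples; `bound_nadh_ratio()` flags pixels whose total NADH
  fraction is ≤ 1e−6 as invalid.
- All simulation entry points take explicit seeds and restore the global
  RNG state (`withr::with_seed`), so pipelines are bit-reproducible.

## Problem sizes used by the test-suite and scripts

The shipped tests and analysis scripts run the depth-series analyses at
128×128 pixels (5 depths, 10 seeds for the trend-sign and ex-vivo suites),
the single-plane recovery checks at 256×256, and the downsampling check at
1024×1024 — sizes at which every statistic of interest is stable while a
full run of the suite stays comfortably interactive. The same code paths
scale unchanged to full-frame rasters.

## Known limitations

Harmonics above 2, modulation-lifetime maps, multi-exponential and global
fitting, FAD/5-component unmixing, spectral unmixing and mosaic stitching
are out of scope. Vendor FLIM formats (.sdt, .ptu) are not read; the
TIFF + JSON-sidecar convention documented in `write_decay_tiff()` is the
package's interchange format, and an adapter to vendor formats would slot
in at `read_decay_tiff()`.
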