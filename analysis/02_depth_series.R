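#!/usr/bin/env Rscript
# Depth-resolved unmixing across skin types.
#
# Runs the full pipeline (simulate -> calibrate -> phasor -> bin + median ->
# unmix -> quantify) on 128x128 phantoms of skin types V and III and
# vitiligo at five epidermal depths, then fits linear depth trends of the
# photon-weighted medians (keratin, melanin) and of the bound-NADH-ratio
# mode. Writes results/depth_summaries.csv and results/depth_trends.csv and
# a phasor plot per depth under results/depth_series_typeV/.
#
# Finding: keratin medians fall and melanin medians rise with depth in the
# pigmented types; vitiligo melanin medians stay at zero and its NADH-ratio
# mode trend is flat, while types III/V drift to lower bound-NADH ratios
# with depth.

library(epiphasor)
dir.create("results", showWarnings = FALSE)

acq <- acquisition_model()
comps <- default_components(acq)
cal <- compute_calibration(
  make_monoexponential_stack(2.5, c(16, 16), 225, acq), 2.5,
  reference_name = "coumarin6")

presets <- c("depth_series_typeV", "depth_series_typeIII",
             "depth_series_vitiligo")
summaries <- list()
trends <- list()
for (preset in presets) {
  ph <- make_phantom(phantom_spec(preset, shape = c(128, 128),
                                  mean_photons = 225, seed = 7),
                     comps, acq)
  ker <- list(); mel <- list(); modes <- numeric(0)
  for (j in seq_along(ph$stacks)) {
    f <- median_filter_phasor(bin_spatial(
      apply_calibration(phasor_transform(ph$stacks[[j]], 1:2), cal), 4L))
    fr <- unmix(f, comps)
    if (preset == "depth_series_typeV") {
      dir.create("results/depth_series_typeV", showWarnings = FALSE)
      save_png(render_phasor_plot(f, 1L, comps)$rgb,
               sprintf("results/depth_series_typeV/phasor_z%02d.png", j))
      save_png(combined_fraction_map(fr),
               sprintf("results/depth_series_typeV/combined_z%02d.png", j))
    }
    z <- ph$spec$depths[j]
    for (comp in comps$name) {
      vs <- violin_summary(fr, comp)
      for (st in c("p10", "p50", "p90", "mode")) {
        summaries[[length(summaries) + 1]] <- data.frame(
          preset = preset, depth_um = z, component = comp, statistic = st,
          value = vs$summary[[st]], n_pixels = vs$summary$n_pixels,
          total_photons = vs$summary$total_photons)
      }
    }
    ker[[j]] <- list(z = z, dist = violin_summary(fr, "keratin"))
    mel[[j]] <- list(z = z, dist = violin_summary(fr, "melanin"))
    r <- bound_nadh_ratio(fr)
    ok <- !is.na(r)
    modes <- c(modes, weighted_mode(r[ok], f$intensity[ok]))
  }
  tk <- depth_trend(ker, "p50")
  tm <- depth_trend(mel, "p50")
  tr <- coef(lm(modes ~ ph$spec$depths))
  trends[[length(trends) + 1]] <- data.frame(
    preset = preset,
    keratin_median_slope = tk$slope,
    melanin_median_slope = tm$slope,
    nadh_ratio_mode_slope = unname(tr[2]))
  cat(sprintf(
    "%-24s keratin slope %+.5f, melanin slope %+.5f, NADH-ratio mode slope %+.5f per um\n",
    preset, tk$slope, tm$slope, unname(tr[2])))
}
write.csv(do.call(rbind, summaries), "results/depth_summaries.csv",
          row.names = FALSE)
write.csv(do.call(rbind, trends), "results/depth_trends.csv",
          row.names = FALSE)
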