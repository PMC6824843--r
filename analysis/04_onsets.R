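#!/usr/bin/env Rscript
# Response onsets: population traces per context (3-SD / 20 ms dwell rule)
# and the paired per-neuron onset contrast.

suppressMessages(library(motorload))

s <- read_session("results/session/trials.csv", "results/session/spikes.csv")
rs <- smooth_spike_trains(s)
em <- epoch_means(rs)
sens <- load_sensitivity_anova(em)
ls_ids <- sens$neuron_id[sens$load_sensitive]

pop <- lapply(c(contra = "contra", ipsi = "ipsi"), function(ctx)
  population_onset(rs, ctx, neuron_ids = ls_ids))
cat(sprintf("population onsets: contra %s ms, ipsi %s ms (lag %s ms, n=%d)\n",
            pop$contra$onset_ms, pop$ipsi$onset_ms,
            pop$ipsi$onset_ms - pop$contra$onset_ms, length(ls_ids)))

on_c <- neuron_onsets(rs, "contra", neuron_ids = ls_ids)
on_i <- neuron_onsets(rs, "ipsi", neuron_ids = ls_ids)
dir.create("results/onsets", recursive = TRUE, showWarnings = FALSE)
utils::write.csv(rbind(on_c, on_i), "results/onsets/neuron_onsets.csv",
                 row.names = FALSE)

fits <- fit_planes(em, "perturbation")
oc <- tryCatch(
  onset_contrast(on_c, on_i,
                 fits[, c("neuron_id", "context", "magnitude_hz_per_nm")]),
  error = function(e) NULL
)
if (!is.null(oc)) {
  cat(sprintf("paired onsets (n=%d): medians %.0f/%.0f ms, %.0f%% contra earlier, z %.1f p %.3g\n",
              oc$n, oc$median_onset_contra, oc$median_onset_ipsi,
              100 * oc$fraction_contra_earlier, oc$z, oc$p))
  cat(sprintf("onset difference vs log magnitude ratio: r %.2f\n",
              oc$r_diff_vs_log_ratio))
  write_report(list(onsets = list(
    population = lapply(pop, function(p)
      list(onset_ms = p$onset_ms, n = p$n_neurons)),
    paired = list(median_contra = oc$median_onset_contra,
                  median_ipsi = oc$median_onset_ipsi,
                  z = oc$z, p = oc$p, n = oc$n,
                  r_diff_vs_log_ratio = oc$r_diff_vs_log_ratio)
  )), "results/onsets/stats.json")
}
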