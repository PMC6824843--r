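#!/usr/bin/env Rscript
# Per-neuron load sensitivity (three-way ANOVA), planar preferred-load fits,
# population tuning-distribution statistics, and the contra/ipsi magnitude
# contrast.

suppressMessages(library(motorload))

s <- read_session("results/session/trials.csv", "results/session/spikes.csv")
rs <- smooth_spike_trains(s)
em <- epoch_means(rs)

sens <- load_sensitivity_anova(em)
fits <- fit_planes(em)
dir.create("results/tuning", recursive = TRUE, showWarnings = FALSE)
utils::write.csv(sens, "results/tuning/load_sensitivity.csv", row.names = FALSE)
utils::write.csv(fits, "results/tuning/planar_fits.csv", row.names = FALSE)

ls_ids <- sens$neuron_id[sens$load_sensitive]
pert <- fits[fits$epoch == "perturbation" & fits$neuron_id %in% ls_ids, ]
stats_out <- list()
for (ctx in c("contra", "ipsi")) {
  ang <- pert$preferred_angle_deg[pert$context == ctx]
  b <- rayleigh_bootstrap_p(ang, "bimodal", n_boot = 1000, seed = 101L)
  stats_out[[ctx]] <- list(bimodal_R = b$R, axis_deg = b$axis_deg, p = b$p,
                           n = length(ang), seed = 101L)
  cat(sprintf("%s: bimodal R %.2f, axis %.0f deg, p %.3f (n=%d)\n",
              ctx, b$R, b$axis_deg, b$p, length(ang)))
}

td <- tuning_difference(pert[pert$context == "contra", ],
                        pert[pert$context == "ipsi", ],
                        n_boot = 1000, seed = 102L)
mc <- magnitude_contrast(pert[pert$context == "contra", ],
                         pert[pert$context == "ipsi", ])
cat(sprintf("load-sensitive: %d/%d neurons\n", length(ls_ids), nrow(sens)))
cat(sprintf("context tuning change: R %.2f, p %.3f\n", td$R, td$p))
cat(sprintf("magnitudes: contra %.1f vs ipsi %.1f Hz/Nm (%.0f%% larger contra, z %.1f)\n",
            mc$median_contra, mc$median_ipsi,
            100 * mc$fraction_contra_larger, mc$z))

write_report(list(tuning = c(stats_out, list(
  tuning_change = list(R = td$R, axis_deg = td$axis_deg, p = td$p,
                       seed = 102L),
  magnitude = list(median_contra = mc$median_contra,
                   median_ipsi = mc$median_ipsi,
                   fraction_contra_larger = mc$fraction_contra_larger,
                   z = mc$z, p = mc$p, n = mc$n)
))), "results/tuning/stats.json")
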