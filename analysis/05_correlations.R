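#!/usr/bin/env Rscript
# Pairwise signal-correlation change between contexts against the
# finite-trial split null (per context, 1000 replicates).

suppressMessages(library(motorload))

s <- read_session("results/session/trials.csv", "results/session/spikes.csv")
rs <- smooth_spike_trains(s)
cms <- build_context_matrices(rs)

cc <- correlation_change(cms$contra, cms$ipsi)
dir.create("results/correlations", recursive = TRUE, showWarnings = FALSE)
utils::write.csv(cc$pairs, "results/correlations/pairs.csv", row.names = FALSE)
cat(sprintf("median |delta r| over %d pairs: %.3f\n",
            nrow(cc$pairs), cc$median_abs_change))

nulls <- lapply(c(contra = "contra", ipsi = "ipsi"), function(ctx) {
  n <- split_trial_null(rs, ctx, n_boot = 1000, seed = 201L,
                        observed = cc$median_abs_change)
  cat(sprintf("%s trial-split null: mean %.3f (sd %.3f), p %.3g\n",
              ctx, n$null_mean, n$null_sd, n$p))
  n
})

write_report(list(correlations = list(
  median_abs_change = cc$median_abs_change,
  nulls = lapply(nulls, function(n)
    list(mean = n$null_mean, sd = n$null_sd, p = n$p, n_boot = n$n_boot,
         seed = n$seed))
)), "results/correlations/stats.json")
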