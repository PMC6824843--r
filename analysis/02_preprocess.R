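#!/usr/bin/env Rscript
# Smooth spike trains with the causal post-spike kernel, compute per-trial
# epoch means, and build the soft-normalized context matrices C and I.

suppressMessages(library(motorload))

s <- read_session("results/session/trials.csv", "results/session/spikes.csv")
rs <- smooth_spike_trains(s, postspike_kernel())
em <- epoch_means(rs)
cms <- build_context_matrices(rs)

dir.create("results/preprocess", recursive = TRUE, showWarnings = FALSE)
utils::write.csv(em, "results/preprocess/epoch_means.csv", row.names = FALSE)
for (ctx in c("contra", "ipsi")) {
  utils::write.csv(as.data.frame(unclass(cms[[ctx]])),
                   sprintf("results/preprocess/context_matrix_%s.csv", ctx),
                   row.names = TRUE)
}

cat(sprintf("rates: %d neurons, aligned window [%d, %d) ms\n",
            length(rs$neuron_ids), min(rs$times_ms), max(rs$times_ms) + 1))
cat(sprintf("context matrices: %d x %d (soft-norm divisors %.1f-%.1f Hz)\n",
            nrow(cms$contra), ncol(cms$contra),
            min(attr(cms$contra, "soft_norm")),
            max(attr(cms$contra, "soft_norm"))))
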