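#!/usr/bin/env Rscript
# Population subspaces: per-context PCA, the alignment index with its
# variance-weighted random-subspace null, joint orthogonal subspaces on the
# Stiefel manifold, projection-difference statistics, and the neuron-weight
# balance check.

suppressMessages(library(motorload))

s <- read_session("results/session/trials.csv", "results/session/spikes.csv")
rs <- smooth_spike_trains(s)
cms <- build_context_matrices(rs)

pca_c <- context_pca(cms$contra, k = 10, other_cm = cms$ipsi)
pca_i <- context_pca(cms$ipsi, k = 10, other_cm = cms$contra)
cat(sprintf("top-10 contra PCs: %.0f%% of contra, %.0f%% of ipsi variance\n",
            100 * pca_c$cum_var_own[10], 100 * pca_c$cum_var_other[10]))
cat(sprintf("top-10 ipsi PCs: %.0f%% of ipsi, %.0f%% of contra variance\n",
            100 * pca_i$cum_var_own[10], 100 * pca_i$cum_var_other[10]))

an <- alignment_null(cms$contra, cms$ipsi, k = 10, n_boot = 1000, seed = 301L)
cat(sprintf("alignment index %.2f (null %.2f +- %.2f, p %.3g)\n",
            an$observed_mean, an$null_mean, an$null_sd, an$p_mean))

cov_c <- context_covariance(cms$contra)
cov_i <- context_covariance(cms$ipsi)
ortho <- joint_orthogonal_subspaces(cov_c, cov_i, d = 3, seed = 302L)
v <- ortho$var_captured
cat(sprintf("orthogonal dims: contra %.0f%%/%.0f%% (own/other), ipsi %.0f%%/%.0f%%\n",
            100 * v$contra_in_contra, 100 * v$contra_in_ipsi,
            100 * v$ipsi_in_ipsi, 100 * v$ipsi_in_contra))

proj <- lapply(c(contra = "contra", ipsi = "ipsi"), function(ref) {
  Q <- if (ref == "contra") ortho$Q_contra else ortho$Q_ipsi
  p <- relative_projection_difference(Q, cms$contra, cms$ipsi, reference = ref,
                                      rs = rs, n_boot = 1000, seed = 303L)
  cat(sprintf("relative difference in %s dims: %.0f%% (95%% CI %.0f-%.0f)\n",
              ref, p$percent, p$ci[1], p$ci[2]))
  p
})

wb <- weight_balance_index(pca_c, pca_i)
cat(sprintf("weight balance: KS D %.3f, p %.2f (n=%d)\n",
            wb$ks_statistic, wb$ks_p, wb$n))

dir.create("results/subspace", recursive = TRUE, showWarnings = FALSE)
utils::write.csv(data.frame(neuron_id = rownames(pca_c$components),
                            pca_c$components),
                 "results/subspace/pcs_contra.csv", row.names = FALSE)
utils::write.csv(data.frame(neuron_id = rownames(pca_i$components),
                            pca_i$components),
                 "results/subspace/pcs_ipsi.csv", row.names = FALSE)
write_report(list(subspace = list(
  variance = list(contra_own = pca_c$cum_var_own[10],
                  contra_other = pca_c$cum_var_other[10],
                  ipsi_own = pca_i$cum_var_own[10],
                  ipsi_other = pca_i$cum_var_other[10]),
  alignment = list(value = an$observed_mean,
                   null_summary = list(mean = an$null_mean, sd = an$null_sd,
                                       p = an$p_mean),
                   seed = an$seed),
  orthogonalization = list(objective = ortho$objective, var_captured = v,
                           seed = 302L),
  relative_difference = lapply(proj, function(p)
    list(value = p$percent, ci = p$ci, p = p$p, seed = p$seed)),
  weight_balance = list(D = wb$ks_statistic, p = wb$ks_p, n = wb$n)
)), "results/subspace/stats.json")
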