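#' Pairwise signal correlations within a context
#'
#' Pearson correlation between every unordered pair of neurons' rows of the
#' soft-normalized, mean-subtracted context matrix (condition-time signal
#' vectors). Pairs involving a constant row are skipped with a warning.
#'
#' @param cm a `context_matrix` from [build_context_matrices()].
#' @return A data frame with `neuron_a`, `neuron_b`, `r`.
#' @export
pairwise_correlations <- function(cm) {
  stopifnot(inherits(cm, "context_matrix"))
  if (nrow(cm) < 2) stop("need at least 2 neurons")
  m <- unclass(cm)
  constant <- apply(m, 1, function(x) stats::sd(x) == 0)
  if (any(constant)) {
    warning("skipping constant rows (undefined correlation): ",
            paste(rownames(m)[constant], collapse = ", "))
  }
  keep <- which(!constant)
  r <- stats::cor(t(m[keep, , drop = FALSE]))
  idx <- which(upper.tri(r), arr.ind = TRUE)
  data.frame(
    neuron_a = rownames(m)[keep][idx[, 1]],
    neuron_b = rownames(m)[keep][idx[, 2]],
    r = r[idx]
  )
}

#' Observed change in pairwise correlations between contexts
#'
#' @param cm_contra,cm_ipsi `context_matrix` objects over the same neurons
#'   in the same order.
#' @return A list: per-pair table with `r_contra`, `r_ipsi`,
#'   `abs_change`, and the `median_abs_change` across pairs.
#' @export
correlation_change <- function(cm_contra, cm_ipsi) {
  if (!identical(rownames(cm_contra), rownames(cm_ipsi))) {
    stop("context matrices cover different neuron sets")
  }
  pc <- pairwise_correlations(cm_contra)
  pi_ <- pairwise_correlations(cm_ipsi)
  key_c <- paste(pc$neuron_a, pc$neuron_b)
  key_i <- paste(pi_$neuron_a, pi_$neuron_b)
  common <- intersect(key_c, key_i)
  pc <- pc[match(common, key_c), ]
  pi_ <- pi_[match(common, key_i), ]
  pairs <- data.frame(
    neuron_a = pc$neuron_a, neuron_b = pc$neuron_b,
    r_contra = pc$r, r_ipsi = pi_$r,
    abs_change = abs(pc$r - pi_$r)
  )
  list(pairs = pairs, median_abs_change = stats::median(pairs$abs_change))
}

#' Trial-split null for the median correlation change
#'
#' Under the null that correlation differences reflect only finite-trial
#' averaging noise, each replicate randomly halves the trials of every load
#' condition within one context (the larger half takes any odd trial),
#' builds two trial-averaged context-matrix variants using the full-data
#' soft-norm divisors, and records the median absolute correlation
#' difference between the halves.
#'
#' @param rs a [smooth_spike_trains()] result.
#' @param context `"contra"` or `"ipsi"`.
#' @param n_boot number of replicates.
#' @param seed integer seed.
#' @param bin_ms,soft_norm_hz as in [build_context_matrices()].
#' @param observed optional observed median absolute change for a p-value.
#' @return A list: `null` samples, `null_mean`, `null_sd`, `p`
#'   (fraction of null at or above `observed`), `n_boot`, `seed`.
#' @export
split_trial_null <- function(rs, context, n_boot = 1000, seed = 1L,
                             bin_ms = 10, soft_norm_hz = 5, observed = NULL) {
  stopifnot(inherits(rs, "rate_series"))
  pt <- rs$windows$perturbation
  sample_t <- seq(pt[1], pt[2] - 1, by = bin_ms)
  sample_idx <- match(sample_t, rs$times_ms)
  n_trials <- vapply(rs$rates[[context]], function(a) dim(a)[3], numeric(1))
  if (any(n_trials < 2)) {
    stop("conditions with fewer than 2 trials: load ",
         paste(which(n_trials < 2) - 1L, collapse = ", "))
  }
  # downsampled per-trial arrays: neurons x bins x trials per condition
  ds <- lapply(rs$rates[[context]],
               function(a) a[, sample_idx, , drop = FALSE])
  divisors <- soft_norm_divisors(rs, soft_norm_hz)

  set.seed(seed)
  null <- vapply(seq_len(n_boot), function(b) {
    h1 <- vector("list", 8)
    h2 <- vector("list", 8)
    for (ci in 1:8) {
      n_tr <- dim(ds[[ci]])[3]
      grp1 <- sample(n_tr, ceiling(n_tr / 2))
      h1[[ci]] <- rowMeans(ds[[ci]][, , grp1, drop = FALSE], dims = 2)
      h2[[ci]] <- rowMeans(ds[[ci]][, , -grp1, drop = FALSE], dims = 2)
    }
    m1 <- context_matrix_from_avgs(h1, divisors, context, sample_t)
    m2 <- context_matrix_from_avgs(h2, divisors, context, sample_t)
    r1 <- suppressWarnings(stats::cor(t(unclass(m1))))
    r2 <- suppressWarnings(stats::cor(t(unclass(m2))))
    stats::median(abs(r1 - r2)[upper.tri(r1)], na.rm = TRUE)
  }, numeric(1))

  list(null = null, null_mean = mean(null), null_sd = stats::sd(null),
       p = if (is.null(observed)) NULL else mean(null >= observed),
       observed = observed, n_boot = n_boot, seed = seed, context = context)
}
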