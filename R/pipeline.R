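#' Pipeline configuration
#'
#' One configuration object drives the full analysis: input session paths or
#' a simulation config, the smoothing kernel, epoch windows, subspace sizes,
#' bootstrap counts, and an explicit seed for every stochastic stage.
#'
#' @param session_dir directory with `trials.csv`/`spikes.csv`, or `NULL`
#'   when `sim` is given.
#' @param sim a [sim_config()] to simulate the input session.
#' @param kernel `"postspike"` or `"gaussian"`.
#' @param gaussian_sd_ms Gaussian kernel width when `kernel = "gaussian"`.
#' @param windows an [epoch_windows()].
#' @param k top principal components per context.
#' @param d orthogonal dimensions per context.
#' @param n_boot bootstrap replicates for every null.
#' @param seeds named list of integer seeds, one per stochastic stage:
#'   `rayleigh`, `correlation_null`, `alignment_null`, `orthogonalization`,
#'   `projection`.
#' @param out_dir output directory for artifacts and `report.json`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(session_dir = NULL, sim = NULL,
                            kernel = c("postspike", "gaussian"),
                            gaussian_sd_ms = 20, windows = epoch_windows(),
                            k = 10, d = 3, n_boot = 1000,
                            seeds = list(rayleigh = 11L, correlation_null = 12L,
                                         alignment_null = 13L,
                                         orthogonalization = 14L,
                                         projection = 15L),
                            out_dir = NULL) {
  kernel <- match.arg(kernel)
  if (is.null(session_dir) && is.null(sim)) {
    stop("either session_dir or sim must be given")
  }
  need <- c("rayleigh", "correlation_null", "alignment_null",
            "orthogonalization", "projection")
  missing_seeds <- setdiff(need, names(seeds))
  if (length(missing_seeds)) {
    stop("missing seeds for stochastic stages: ",
         paste(missing_seeds, collapse = ", "))
  }
  structure(list(session_dir = session_dir, sim = sim, kernel = kernel,
                 gaussian_sd_ms = gaussian_sd_ms, windows = windows,
                 k = k, d = d, n_boot = n_boot, seeds = seeds,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages in dependency order: ingest or simulate the session; smooth spike
#' trains and build epoch means and context matrices; per-neuron
#' load-sensitivity ANOVA, planar fits and population tuning statistics;
#' single-neuron and population onsets; pairwise correlation change with its
#' trial-split nulls; PCA, alignment index with its variance-weighted null,
#' joint orthogonalization, projection differences, and the weight-balance
#' check. Reruns with identical config and seeds reproduce the report
#' exactly.
#'
#' @param config a [pipeline_config()].
#' @return A named list of stage results (also written to
#'   `out_dir/report.json` and CSV tables when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  # --- ingest ---------------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- simulate_session(config$sim)
    s <- sim$session
  } else {
    s <- read_session(file.path(config$session_dir, "trials.csv"),
                      file.path(config$session_dir, "spikes.csv"))
  }
  kern <- if (config$kernel == "postspike") postspike_kernel() else
    gaussian_kernel(config$gaussian_sd_ms)

  # --- preprocessing --------------------------------------------------------
  rs <- smooth_spike_trains(s, kern, config$windows)
  em <- epoch_means(rs)
  cms <- build_context_matrices(rs)

  # --- tuning ---------------------------------------------------------------
  sens <- load_sensitivity_anova(em)
  fits <- fit_planes(em)
  ls_ids <- sens$neuron_id[sens$load_sensitive]
  pert <- fits[fits$epoch == "perturbation", ]
  pert_ls <- pert[pert$neuron_id %in% ls_ids, ]
  bimodal <- lapply(c(contra = "contra", ipsi = "ipsi"), function(ctx) {
    ang <- pert_ls$preferred_angle_deg[pert_ls$context == ctx]
    rayleigh_bootstrap_p(ang, "bimodal", n_boot = config$n_boot,
                         seed = config$seeds$rayleigh)
  })
  sig_any <- unique(pert$neuron_id[pert$p_value < 0.05])
  magc <- magnitude_contrast(
    pert[pert$context == "contra" & pert$neuron_id %in% sig_any, ],
    pert[pert$context == "ipsi" & pert$neuron_id %in% sig_any, ]
  )
  tdiff <- tuning_difference(
    pert_ls[pert_ls$context == "contra", ],
    pert_ls[pert_ls$context == "ipsi", ],
    n_boot = config$n_boot, seed = config$seeds$rayleigh
  )

  # --- onsets ---------------------------------------------------------------
  pop_on <- lapply(c(contra = "contra", ipsi = "ipsi"), function(ctx) {
    population_onset(rs, ctx, neuron_ids = ls_ids)
  })
  on_c <- neuron_onsets(rs, "contra", neuron_ids = ls_ids)
  on_i <- neuron_onsets(rs, "ipsi", neuron_ids = ls_ids)
  onset_stats <- tryCatch(
    onset_contrast(on_c, on_i, pert[, c("neuron_id", "context",
                                        "magnitude_hz_per_nm")]),
    error = function(e) list(error = conditionMessage(e))
  )

  # --- correlations ---------------------------------------------------------
  cchange <- correlation_change(cms$contra, cms$ipsi)
  cnull <- lapply(c(contra = "contra", ipsi = "ipsi"), function(ctx) {
    split_trial_null(rs, ctx, n_boot = config$n_boot,
                     seed = config$seeds$correlation_null,
                     observed = cchange$median_abs_change)
  })

  # --- subspaces ------------------------------------------------------------
  anull <- alignment_null(cms$contra, cms$ipsi, k = config$k,
                          n_boot = config$n_boot,
                          seed = config$seeds$alignment_null)
  cov_c <- context_covariance(cms$contra)
  cov_i <- context_covariance(cms$ipsi)
  ortho <- joint_orthogonal_subspaces(cov_c, cov_i, d = config$d,
                                      seed = config$seeds$orthogonalization)
  proj <- lapply(c(contra = "contra", ipsi = "ipsi"), function(ref) {
    Q <- if (ref == "contra") ortho$Q_contra else ortho$Q_ipsi
    relative_projection_difference(Q, cms$contra, cms$ipsi, reference = ref,
                                   rs = rs, n_boot = config$n_boot,
                                   seed = config$seeds$projection)
  })
  wbal <- weight_balance_index(context_pca(cms$contra, config$k),
                               context_pca(cms$ipsi, config$k))

  results <- list(
    session = list(
      n_neurons = length(rs$neuron_ids), n_trials = nrow(s$trials),
      simulated = !is.null(config$sim)
    ),
    tuning = list(
      n_load_sensitive = sum(sens$load_sensitive),
      fraction_load_sensitive = mean(sens$load_sensitive),
      bimodal_rayleigh = lapply(bimodal, function(b)
        list(value = b$R, axis_deg = b$axis_deg, p = b$p, seed = b$seed)),
      magnitude = list(
        value = magc$median_contra / magc$median_ipsi,
        median_contra = magc$median_contra, median_ipsi = magc$median_ipsi,
        fraction_contra_larger = magc$fraction_contra_larger,
        z = magc$z, p = magc$p, n = magc$n
      ),
      tuning_change = list(value = tdiff$R, axis_deg = tdiff$axis_deg,
                           p = tdiff$p, seed = tdiff$seed)
    ),
    onsets = list(
      population = lapply(pop_on, function(o)
        list(value = o$onset_ms, n_neurons = o$n_neurons)),
      paired = if (!is.null(onset_stats$error)) onset_stats else list(
        median_contra = onset_stats$median_onset_contra,
        median_ipsi = onset_stats$median_onset_ipsi,
        median_difference = onset_stats$median_difference,
        fraction_contra_earlier = onset_stats$fraction_contra_earlier,
        z = onset_stats$z, p = onset_stats$p, n = onset_stats$n,
        r_diff_vs_log_ratio = onset_stats$r_diff_vs_log_ratio
      )
    ),
    correlations = list(
      median_abs_change = list(
        value = cchange$median_abs_change,
        null_summary = lapply(cnull, function(x)
          list(mean = x$null_mean, sd = x$null_sd, p = x$p)),
        seed = config$seeds$correlation_null
      )
    ),
    subspace = list(
      alignment = list(
        value = anull$observed_mean,
        A_contra_on_ipsi = anull$A_contra_on_ipsi,
        A_ipsi_on_contra = anull$A_ipsi_on_contra,
        null_summary = list(mean = anull$null_mean, sd = anull$null_sd,
                            p = anull$p_mean),
        seed = anull$seed
      ),
      orthogonalization = list(
        objective = ortho$objective,
        var_captured = ortho$var_captured,
        relative_difference = lapply(proj, function(p)
          list(value = p$percent, ci = p$ci, p = p$p, seed = p$seed))
      ),
      weight_balance = list(ks_statistic = wbal$ks_statistic,
                            ks_p = wbal$ks_p, n = wbal$n)
    ),
    peripheral = list(note = "no EMG or kinematic channels in this session"),
    config = list(kernel = config$kernel, k = config$k, d = config$d,
                  n_boot = config$n_boot, seeds = config$seeds,
                  sim_seed = if (!is.null(config$sim)) config$sim$seed else NULL)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fits, file.path(config$out_dir, "planar_fits.csv"),
                     row.names = FALSE)
    utils::write.csv(rbind(on_c, on_i),
                     file.path(config$out_dir, "onsets.csv"),
                     row.names = FALSE)
    utils::write.csv(cchange$pairs,
                     file.path(config$out_dir, "correlation_pairs.csv"),
                     row.names = FALSE)
    write_report(results, file.path(config$out_dir, "report.json"))
  }
  invisible(results)
}
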