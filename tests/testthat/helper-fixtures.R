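# shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# mid-sized simulated session shared across module tests
demo_sim <- function() {
  cached("demo_sim", simulate_session(
    sim_config(n_neurons = 30, n_trials_per_condition = 6, seed = 42)
  ))
}

demo_rates <- function() {
  cached("demo_rates", smooth_spike_trains(demo_sim()$session))
}

demo_cms <- function() {
  cached("demo_cms", build_context_matrices(demo_rates()))
}

demo_epoch_means <- function() {
  cached("demo_em", epoch_means(demo_rates()))
}

# hand-built minimal session: n neurons, one trial per (context, load) cell,
# regular spikes so everything is deterministic
tiny_session <- function(n_neurons = 3, trials_per_cell = 1) {
  loads <- canonical_load_set()
  grid <- expand.grid(context = c("contra", "ipsi"), load = 0:7,
                      rep = seq_len(trials_per_cell),
                      stringsAsFactors = FALSE)
  trials <- data.frame(
    trial_id = seq_len(nrow(grid)),
    context = grid$context,
    shoulder_torque_nm = loads$shoulder_torque_nm[grid$load + 1],
    elbow_torque_nm = loads$elbow_torque_nm[grid$load + 1],
    perturb_time_ms = 600,
    trial_end_ms = 1950
  )
  spikes <- do.call(rbind, lapply(seq_len(nrow(trials)), function(tr) {
    do.call(rbind, lapply(seq_len(n_neurons), function(ni) {
      times <- seq(10 * ni, 1940, by = 40 + 5 * ni)
      data.frame(neuron_id = sprintf("n%02d", ni), trial_id = tr,
                 spike_time_ms = times)
    }))
  }))
  session(trials, spikes)
}

# rate_series with caller-chosen deterministic rates: f(neuron, context,
# load_index, t_ms) in Hz, identical across trials unless noise_sd > 0
manual_rate_series <- function(n_neurons, n_trials, f, noise_sd = 0,
                               times = seq(-200, 299), steady_hz = 5) {
  ctxs <- c("contra", "ipsi")
  rates <- list(); steady <- list(); avg <- list(); trial_ids <- list()
  ids <- sprintf("n%02d", seq_len(n_neurons))
  tid <- 0L
  for (ctx in ctxs) {
    rates[[ctx]] <- vector("list", 8)
    steady[[ctx]] <- vector("list", 8)
    avg[[ctx]] <- vector("list", 8)
    trial_ids[[ctx]] <- vector("list", 8)
    for (ci in 1:8) {
      base <- t(vapply(seq_len(n_neurons),
                       function(ni) f(ni, ctx, ci - 1L, times),
                       numeric(length(times))))
      arr <- array(0, c(n_neurons, length(times), n_trials))
      for (k in seq_len(n_trials)) {
        arr[, , k] <- pmax(base + if (noise_sd > 0)
          matrix(stats::rnorm(length(base), 0, noise_sd), n_neurons) else 0, 0)
      }
      rates[[ctx]][[ci]] <- arr
      avg[[ctx]][[ci]] <- rowMeans(arr, dims = 2)
      steady[[ctx]][[ci]] <- matrix(steady_hz, n_neurons, n_trials)
      trial_ids[[ctx]][[ci]] <- tid + seq_len(n_trials)
      tid <- tid + n_trials
    }
  }
  structure(
    list(neuron_ids = ids, times_ms = times, windows = epoch_windows(),
         kernel = list(name = "manual", dt_ms = 1),
         loads = canonical_load_set(),
         rates = rates, avg = avg, steady = steady, trial_ids = trial_ids),
    class = "rate_series"
  )
}

# fresh scratch directory under the session tempdir
withr_local_tempdir <- function() {
  d <- tempfile("fixture")
  dir.create(d)
  d
}

# random symmetric PSD matrix of given size and rank
random_psd <- function(n, rank = n, scale = 1) {
  w <- matrix(stats::rnorm(n * rank), n, rank)
  scale * tcrossprod(w) / rank
}

# evaluate the joint-orthogonalization objective for given bases
joint_objective <- function(Q_c, Q_i, cov_c, cov_i, d = ncol(Q_c)) {
  s_c <- sum(eigen(cov_c, symmetric = TRUE, only.values = TRUE)$values[1:d])
  s_i <- sum(eigen(cov_i, symmetric = TRUE, only.values = TRUE)$values[1:d])
  (sum(Q_c * (cov_c %*% Q_c)) / s_c + sum(Q_i * (cov_i %*% Q_i)) / s_i) / 2
}
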