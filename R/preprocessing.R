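#' Causal post-spike-potential smoothing kernel
#'
#' `k(t) = (1 - exp(-t / rise)) * exp(-t / fall)` for `t >= 0` and zero
#' before the spike, normalized to unit area at resolution `dt_ms`. The
#' kernel is causal: a spike only influences the rate estimate after it
#' occurs, which avoids backward bias in onset estimates. Support is
#' truncated where the kernel falls below `1e-6` of its maximum.
#'
#' @param rise_ms,fall_ms rise and fall time constants in ms
#'   (`rise_ms < fall_ms`, both positive).
#' @param dt_ms sampling resolution in ms.
#' @return An object of class `rate_kernel`: weights (density per ms), the
#'   index of lag zero, and the resolution.
#' @export
postspike_kernel <- function(rise_ms = 1, fall_ms = 20, dt_ms = 1) {
  if (rise_ms <= 0 || fall_ms <= 0) stop("time constants must be positive")
  if (rise_ms >= fall_ms) stop("rise_ms must be smaller than fall_ms")
  # unnormalized peak is at t = rise * log(1 + fall/rise); truncate where the
  # tail drops below 1e-6 of the peak
  t_peak <- rise_ms * log(1 + fall_ms / rise_ms)
  t_max <- t_peak + fall_ms * log(1e6)
  t <- seq(0, t_max, by = dt_ms)
  k <- (1 - exp(-t / rise_ms)) * exp(-t / fall_ms)
  k[k < 1e-6 * max(k)] <- 0
  keep <- seq_len(max(which(k > 0)))
  t <- t[keep]
  k <- k[keep]
  k <- k / (sum(k) * dt_ms)
  structure(list(weights = k, lag0 = 1L, dt_ms = dt_ms, times_ms = t,
                 name = "postspike"),
            class = "rate_kernel")
}

#' Gaussian smoothing kernel
#'
#' Non-causal Gaussian kernel (support truncated at 4 standard deviations),
#' normalized to unit area, for comparison with analyses that use Gaussian
#' rate estimates.
#'
#' @param sd_ms standard deviation in ms.
#' @param dt_ms sampling resolution in ms.
#' @return A `rate_kernel`.
#' @export
gaussian_kernel <- function(sd_ms = 20, dt_ms = 1) {
  if (sd_ms <= 0) stop("sd_ms must be positive")
  t <- seq(-4 * sd_ms, 4 * sd_ms, by = dt_ms)
  k <- exp(-0.5 * (t / sd_ms)^2)
  k <- k / (sum(k) * dt_ms)
  structure(list(weights = k, lag0 = which(t == 0), dt_ms = dt_ms,
                 times_ms = t, name = "gaussian"),
            class = "rate_kernel")
}

#' Smooth spike trains into perturbation-aligned firing-rate traces
#'
#' Each trial's spike delta train is convolved with the kernel (rates in Hz)
#' over the whole trial, then realigned to the perturbation onset. The
#' aligned window spans `[baseline start, perturbation end)` at 1 ms
#' resolution; the steady-state epoch is summarized per trial by its mean
#' rate. Trials too short for the requested windows are excluded with a
#' warning.
#'
#' @param s a [session()].
#' @param kernel a `rate_kernel` ([postspike_kernel()] or
#'   [gaussian_kernel()]).
#' @param windows an [epoch_windows()].
#' @return An object of class `rate_series`: per context and load condition,
#'   trial-resolved rate arrays (`neurons x time x trials`), trial-averaged
#'   traces, per-trial steady-state means, and bookkeeping.
#' @export
smooth_spike_trains <- function(s, kernel = postspike_kernel(),
                                windows = epoch_windows()) {
  stopifnot(inherits(s, "session"), inherits(kernel, "rate_kernel"))
  if (kernel$dt_ms != 1) stop("rate traces are built at 1 ms resolution")
  trials <- s$trials
  win <- c(windows$baseline[1], windows$perturbation[2])
  neuron_ids <- sort(unique(s$spikes$neuron_id))
  n <- length(neuron_ids)

  too_short <- trials$perturb_time_ms + win[1] < 0 |
    trials$perturb_time_ms + win[2] > trials$trial_end_ms
  if (any(too_short)) {
    warning("excluding trials too short for the requested windows: ",
            paste(trials$trial_id[too_short], collapse = ", "))
    trials <- trials[!too_short, , drop = FALSE]
  }

  w_idx <- seq(win[1], win[2] - 1)           # aligned sample times in ms
  spl <- split(seq_len(nrow(s$spikes)), factor(s$spikes$trial_id,
                                               levels = trials$trial_id))
  rates <- list()
  steady <- list()
  trial_ids <- list()
  for (ctx in c("contra", "ipsi")) {
    rates[[ctx]] <- vector("list", 8)
    steady[[ctx]] <- vector("list", 8)
    trial_ids[[ctx]] <- vector("list", 8)
  }

  for (row in seq_len(nrow(trials))) {
    tr <- trials[row, ]
    t_end <- tr$trial_end_ms
    rows <- spl[[as.character(tr$trial_id)]]
    rate <- trial_rates(s$spikes[rows, , drop = FALSE], neuron_ids,
                        t_end, kernel)
    sel <- tr$perturb_time_ms + w_idx + 1L      # bin t covers [t, t+1)
    aligned <- rate[, sel, drop = FALSE]
    ss <- rowMeans(rate[, seq(t_end - windows$steady_state_ms + 1, t_end),
                        drop = FALSE])
    ci <- tr$load_index + 1L
    ctx <- tr$context
    rates[[ctx]][[ci]] <- c(rates[[ctx]][[ci]], list(aligned))
    steady[[ctx]][[ci]] <- c(steady[[ctx]][[ci]], list(ss))
    trial_ids[[ctx]][[ci]] <- c(trial_ids[[ctx]][[ci]], tr$trial_id)
  }

  avg <- list()
  for (ctx in c("contra", "ipsi")) {
    avg[[ctx]] <- vector("list", 8)
    for (ci in 1:8) {
      if (length(rates[[ctx]][[ci]]) == 0) next
      arr <- simplify2array(rates[[ctx]][[ci]])
      if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
      rates[[ctx]][[ci]] <- arr
      steady[[ctx]][[ci]] <- do.call(cbind, steady[[ctx]][[ci]])
      avg[[ctx]][[ci]] <- rowMeans(arr, dims = 2)
    }
  }

  structure(
    list(neuron_ids = neuron_ids, times_ms = w_idx, windows = windows,
         kernel = kernel[c("name", "dt_ms")], loads = canonical_load_set(),
         rates = rates, avg = avg, steady = steady, trial_ids = trial_ids),
    class = "rate_series"
  )
}

# smoothed rates (Hz) for one trial: neurons x t_end matrix, FFT convolution
trial_rates <- function(spikes, neuron_ids, t_end, kernel) {
  n <- length(neuron_ids)
  counts <- matrix(0, t_end, n)
  if (nrow(spikes)) {
    ni <- match(spikes$neuron_id, neuron_ids)
    ti <- floor(spikes$spike_time_ms) + 1L
    ti[ti > t_end] <- t_end
    idx <- ti + (ni - 1L) * t_end
    counts <- matrix(tabulate(idx, nbins = t_end * n), t_end, n)
  }
  K <- length(kernel$weights)
  L <- stats::nextn(t_end + K, c(2, 3))
  kf <- stats::fft(c(kernel$weights, numeric(L - K)))
  # pack column pairs into complex columns: one transform smooths two neurons
  n2 <- ceiling(n / 2)
  pad <- matrix(0, L, 2 * n2)
  pad[seq_len(t_end), seq_len(n)] <- counts
  zc <- pad[, seq_len(n2) * 2 - 1, drop = FALSE] +
    1i * pad[, seq_len(n2) * 2, drop = FALSE]
  conv <- stats::mvfft(stats::mvfft(zc) * kf, inverse = TRUE) / L
  z <- matrix(0, L, 2 * n2)
  z[, seq_len(n2) * 2 - 1] <- Re(conv)
  z[, seq_len(n2) * 2] <- Im(conv)
  shift <- kernel$lag0 - 1L
  rate <- z[seq_len(t_end) + shift, seq_len(n), drop = FALSE] * 1000
  rate[rate < 1e-9] <- 0           # floor FFT round-off so silence is exact
  t(rate)
}

#' @export
print.rate_series <- function(x, ...) {
  n_tr <- sum(vapply(x$trial_ids, function(ctx) sum(lengths(ctx)), numeric(1)))
  cat(sprintf("<rate_series> %d neurons, %d trials, window [%d, %d) ms, %s kernel\n",
              length(x$neuron_ids), n_tr, min(x$times_ms), max(x$times_ms) + 1,
              x$kernel$name))
  invisible(x)
}

#' Per-trial epoch mean rates
#'
#' Arithmetic mean of each trial's smoothed rate over the baseline and
#' perturbation windows, plus the stored steady-state epoch mean.
#'
#' @param rs a [smooth_spike_trains()] result.
#' @param windows an [epoch_windows()]; must lie within the aligned window
#'   used to build `rs`.
#' @return A data frame with one row per neuron, context, load, and trial,
#'   and columns `baseline`, `perturbation`, `steady` (Hz).
#' @export
epoch_means <- function(rs, windows = rs$windows) {
  stopifnot(inherits(rs, "rate_series"))
  bl_idx <- which(rs$times_ms >= windows$baseline[1] &
                    rs$times_ms < windows$baseline[2])
  pt_idx <- which(rs$times_ms >= windows$perturbation[1] &
                    rs$times_ms < windows$perturbation[2])
  if (!length(bl_idx) || !length(pt_idx)) {
    stop("requested epoch windows are empty within the aligned rate window")
  }
  out <- list()
  for (ctx in c("contra", "ipsi")) {
    for (ci in 1:8) {
      arr <- rs$rates[[ctx]][[ci]]
      if (is.null(arr)) next
      n_tr <- dim(arr)[3]
      bl <- colMeans(aperm(arr[, bl_idx, , drop = FALSE], c(2, 1, 3)))
      pt <- colMeans(aperm(arr[, pt_idx, , drop = FALSE], c(2, 1, 3)))
      out[[length(out) + 1L]] <- data.frame(
        neuron_id = rep(rs$neuron_ids, n_tr),
        context = ctx,
        load_index = ci - 1L,
        trial_id = rep(rs$trial_ids[[ctx]][[ci]], each = length(rs$neuron_ids)),
        baseline = as.vector(bl),
        perturbation = as.vector(pt),
        steady = as.vector(rs$steady[[ctx]][[ci]])
      )
    }
  }
  do.call(rbind, out)
}

#' Build the soft-normalized context matrices
#'
#' Trial-averaged perturbation-epoch traces are point-sampled every `bin_ms`
#' (30 samples for a 300 ms epoch), each neuron's rates (both contexts
#' jointly) are divided by its maximum trial-averaged rate plus
#' `soft_norm_hz`, and within each context the mean across the eight load
#' conditions is subtracted at every time bin. The result per context is the
#' neurons x (conditions * time bins) matrix the population analyses consume.
#'
#' @param rs a [smooth_spike_trains()] result covering the perturbation
#'   epoch for both contexts.
#' @param bin_ms sampling interval in ms.
#' @param soft_norm_hz constant added to the maximum rate (5 spikes/s).
#' @return A list with `contra` and `ipsi` entries of class
#'   `context_matrix`, each carrying its soft-norm divisors and a
#'   (condition, time) column map as attributes.
#' @export
build_context_matrices <- function(rs, bin_ms = 10, soft_norm_hz = 5) {
  stopifnot(inherits(rs, "rate_series"))
  for (ctx in c("contra", "ipsi")) {
    miss <- which(vapply(rs$avg[[ctx]], is.null, logical(1)))
    if (length(miss)) {
      stop("missing conditions: ",
           paste(sprintf("(%s, load %d)", ctx, miss - 1L), collapse = ", "))
    }
  }
  pt <- rs$windows$perturbation
  sample_t <- seq(pt[1], pt[2] - 1, by = bin_ms)
  sample_idx <- match(sample_t, rs$times_ms)
  if (anyNA(sample_idx)) stop("perturbation window not covered by rate window")

  divisors <- soft_norm_divisors(rs, soft_norm_hz)
  out <- list()
  for (ctx in c("contra", "ipsi")) {
    ds <- lapply(rs$avg[[ctx]], function(m) m[, sample_idx, drop = FALSE])
    out[[ctx]] <- context_matrix_from_avgs(ds, divisors, ctx, sample_t)
  }
  out
}

# per-neuron soft-normalization divisor: max trial-averaged rate across both
# contexts, all conditions and aligned times, plus the soft constant
soft_norm_divisors <- function(rs, soft_norm_hz = 5) {
  mx <- rep(-Inf, length(rs$neuron_ids))
  for (ctx in c("contra", "ipsi")) {
    for (ci in 1:8) {
      m <- rs$avg[[ctx]][[ci]]
      if (!is.null(m)) mx <- pmax(mx, apply(m, 1, max))
    }
  }
  stats::setNames(mx + soft_norm_hz, rs$neuron_ids)
}

# assemble one context matrix from per-condition downsampled trial averages
context_matrix_from_avgs <- function(ds, divisors, ctx, sample_t) {
  norm <- lapply(ds, function(m) m / divisors)
  cond_mean <- Reduce(`+`, norm) / length(norm)
  centred <- lapply(norm, function(m) m - cond_mean)
  m <- do.call(cbind, centred)
  rownames(m) <- names(divisors)
  structure(
    m,
    context = ctx,
    soft_norm = divisors,
    condition_mean = cond_mean,
    columns = data.frame(
      load_index = rep(seq_along(ds) - 1L, each = length(sample_t)),
      time_ms = rep(sample_t, length(ds))
    ),
    class = c("context_matrix", "matrix")
  )
}
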