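#' Best-load trial-averaged trace for one neuron
#'
#' Finds the load combination with the largest absolute change of the
#' perturbation-epoch mean from baseline, then averages all trials from that
#' load and its two 45-degree neighbours. Ties are broken by the lower load
#' index.
#'
#' @param rs a [smooth_spike_trains()] result.
#' @param neuron_id neuron identifier.
#' @param context `"contra"` or `"ipsi"`.
#' @return A list: `trace` (Hz, over `rs$times_ms`), `best_load_index`,
#'   `selected_loads`, and `tie` flag.
#' @export
best_load_average <- function(rs, neuron_id, context) {
  stopifnot(inherits(rs, "rate_series"))
  ni <- match(neuron_id, rs$neuron_ids)
  if (is.na(ni)) stop("unknown neuron_id: ", neuron_id)
  w <- rs$windows
  bl_idx <- which(rs$times_ms >= w$baseline[1] & rs$times_ms < w$baseline[2])
  pt_idx <- which(rs$times_ms >= w$perturbation[1] &
                    rs$times_ms < w$perturbation[2])
  change <- vapply(1:8, function(ci) {
    m <- rs$avg[[context]][[ci]]
    abs(mean(m[ni, pt_idx]) - mean(m[ni, bl_idx]))
  }, numeric(1))
  best <- which(change == max(change))
  tie <- length(best) > 1
  best <- min(best)
  sel <- ((best - 1 + c(-1, 0, 1)) %% 8) + 1
  # pool all trials across the three neighbouring loads
  total <- 0
  n_tr <- 0
  for (ci in sel) {
    arr <- rs$rates[[context]][[ci]]
    total <- total + rowSums(arr[ni, , , drop = FALSE], dims = 2)
    n_tr <- n_tr + dim(arr)[3]
  }
  list(trace = as.numeric(total / n_tr), best_load_index = best - 1L,
       selected_loads = sel - 1L, tie = tie)
}

#' Threshold-crossing response onset of a rate trace
#'
#' The onset is the first post-load sample whose deviation from the baseline
#' mean exceeds `k_sd` baseline standard deviations and stays beyond that
#' threshold for `dwell_ms` consecutive milliseconds. The criterion is
#' two-sided by default (responses may be excitatory or inhibitory).
#'
#' @param trace rate trace in Hz sampled at 1 ms.
#' @param times_ms sample times relative to load onset.
#' @param baseline_window window used for the baseline mean and SD.
#' @param search_window window searched for an onset.
#' @param k_sd threshold in baseline standard deviations.
#' @param dwell_ms consecutive ms the threshold must hold.
#' @param two_sided if `FALSE`, only positive deviations count.
#' @return A list: `onset_ms` (`NA` if the threshold never held),
#'   `baseline_mean`, `baseline_sd`, `degenerate` (baseline SD of zero).
#' @export
detect_onset <- function(trace, times_ms, baseline_window = c(-200, 0),
                         search_window = c(0, 300), k_sd = 3, dwell_ms = 20,
                         two_sided = TRUE) {
  stopifnot(length(trace) == length(times_ms))
  bl <- trace[times_ms >= baseline_window[1] & times_ms < baseline_window[2]]
  if (!length(bl)) stop("baseline window is empty")
  search_idx <- which(times_ms >= search_window[1] & times_ms < search_window[2])
  if (length(search_idx) < dwell_ms) {
    stop("trace shorter than the dwell window after load onset")
  }
  mu <- mean(bl)
  sd_bl <- stats::sd(bl)
  if (!is.finite(sd_bl) || sd_bl == 0) {
    return(list(onset_ms = NA_real_, baseline_mean = mu, baseline_sd = sd_bl,
                degenerate = TRUE))
  }
  dev <- trace[search_idx] - mu
  above <- if (two_sided) abs(dev) > k_sd * sd_bl else dev > k_sd * sd_bl
  onset <- NA_real_
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  ok <- which(run$values & run$lengths >= dwell_ms)
  if (length(ok)) onset <- times_ms[search_idx[starts[ok[1]]]]
  list(onset_ms = onset, baseline_mean = mu, baseline_sd = sd_bl,
       degenerate = FALSE)
}

#' Onsets for a set of neurons
#'
#' Applies [best_load_average()] and [detect_onset()] per neuron.
#'
#' @param rs a [smooth_spike_trains()] result.
#' @param context `"contra"` or `"ipsi"`.
#' @param neuron_ids neurons to process (default all).
#' @param ... passed to [detect_onset()].
#' @return A data frame with `neuron_id`, `context`, `onset_ms`,
#'   `best_load_index`, `baseline_mean`, `baseline_sd`.
#' @export
neuron_onsets <- function(rs, context, neuron_ids = rs$neuron_ids, ...) {
  rows <- lapply(neuron_ids, function(id) {
    bla <- best_load_average(rs, id, context)
    det <- detect_onset(bla$trace, rs$times_ms,
                        baseline_window = rs$windows$baseline,
                        search_window = rs$windows$perturbation, ...)
    data.frame(neuron_id = id, context = context, onset_ms = det$onset_ms,
               best_load_index = bla$best_load_index,
               baseline_mean = det$baseline_mean,
               baseline_sd = det$baseline_sd)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Population response onset
#'
#' Each neuron contributes its best-load-average change from baseline,
#' signed so its perturbation-epoch mean change is positive (preventing
#' cancellation of excited and inhibited neurons); the onset of the
#' across-neuron average trace is then detected with the same
#' threshold-and-dwell rule. With `selection = "split"` (the default) the
#' best load and the response sign are chosen on one half of the trials
#' while the averaged trace is built from the other half: selecting on the
#' trace's own trials couples the sign to its noise and imprints a spurious
#' step at the load onset once many weakly responding neurons are averaged.
#'
#' @param rs a [smooth_spike_trains()] result.
#' @param context `"contra"` or `"ipsi"`.
#' @param neuron_ids neurons to include (at least 2, typically the
#'   load-sensitive set).
#' @param selection `"split"` for split-half selection, `"all"` to select
#'   and average on all trials.
#' @param ... passed to [detect_onset()].
#' @return A list: `onset_ms`, `trace` (population mean change, Hz),
#'   `baseline_mean`, `baseline_sd`, `n_neurons`.
#' @export
population_onset <- function(rs, context, neuron_ids = rs$neuron_ids,
                             selection = c("split", "all"), ...) {
  stopifnot(length(neuron_ids) >= 2)
  selection <- match.arg(selection)
  w <- rs$windows
  bl_idx <- which(rs$times_ms >= w$baseline[1] & rs$times_ms < w$baseline[2])
  pt_idx <- which(rs$times_ms >= w$perturbation[1] &
                    rs$times_ms < w$perturbation[2])
  can_split <- selection == "split" &&
    all(vapply(rs$rates[[context]], function(a) dim(a)[3], numeric(1)) >= 2)
  traces <- vapply(neuron_ids, function(id) {
    if (can_split) {
      sel <- split_best_load_delta(rs, id, context, bl_idx, pt_idx)
      delta <- sel$delta
      sgn <- sel$sgn
    } else {
      tr <- best_load_average(rs, id, context)$trace
      delta <- tr - mean(tr[bl_idx])
      sgn <- sign(mean(delta[pt_idx]))
    }
    if (sgn == 0) sgn <- 1
    sgn * delta
  }, numeric(length(rs$times_ms)))
  pop <- rowMeans(traces)
  det <- detect_onset(pop, rs$times_ms, baseline_window = w$baseline,
                      search_window = w$perturbation, ...)
  list(onset_ms = det$onset_ms, trace = pop, baseline_mean = det$baseline_mean,
       baseline_sd = det$baseline_sd, n_neurons = length(neuron_ids),
       selection = if (can_split) "split" else "all")
}

# split-half best-load selection: odd trials pick the load and sign, even
# trials form the averaged change trace
split_best_load_delta <- function(rs, id, context, bl_idx, pt_idx) {
  ni <- match(id, rs$neuron_ids)
  sel_avg <- function(ci, half) {
    a <- rs$rates[[context]][[ci]]
    n_tr <- dim(a)[3]
    keep <- if (half == "odd") seq(1, n_tr, 2) else seq(2, n_tr, 2)
    rowMeans(a[ni, , keep, drop = FALSE], dims = 2)[1, ]
  }
  change <- vapply(1:8, function(ci) {
    m <- sel_avg(ci, "odd")
    mean(m[pt_idx]) - mean(m[bl_idx])
  }, numeric(1))
  best <- min(which(abs(change) == max(abs(change))))
  loads <- ((best - 1 + c(-1, 0, 1)) %% 8) + 1
  trace <- rowMeans(vapply(loads, sel_avg, numeric(length(rs$times_ms)),
                           half = "even"))
  # the best load's own change is the most reliable sign estimate
  sgn <- sign(change[best])
  list(delta = trace - mean(trace[bl_idx]), sgn = sgn)
}

#' Contrast of response onsets between contexts
#'
#' Pairs neurons with defined onsets in both contexts: median onsets, the
#' Wilcoxon signed-rank statistic on the onset differences, the correlation
#' between the onset difference and the log magnitude ratio, and
#' within-context magnitude-onset correlations.
#'
#' @param onsets_contra,onsets_ipsi data frames from [neuron_onsets()].
#' @param magnitudes data frame with `neuron_id`, `context`,
#'   `magnitude_hz_per_nm` (planar-fit magnitudes).
#' @return A list of paired statistics.
#' @export
onset_contrast <- function(onsets_contra, onsets_ipsi, magnitudes) {
  oc <- onsets_contra[!is.na(onsets_contra$onset_ms), ]
  oi <- onsets_ipsi[!is.na(onsets_ipsi$onset_ms), ]
  common <- intersect(oc$neuron_id, oi$neuron_id)
  if (length(common) < 5) stop("need at least 5 neurons with onsets in both contexts")
  on_c <- oc$onset_ms[match(common, oc$neuron_id)]
  on_i <- oi$onset_ms[match(common, oi$neuron_id)]
  mag <- function(ctx) {
    m <- magnitudes[magnitudes$context == ctx, ]
    m$magnitude_hz_per_nm[match(common, m$neuron_id)]
  }
  mag_c <- mag("contra")
  mag_i <- mag("ipsi")
  wt <- signed_rank(on_c - on_i)
  list(
    median_onset_contra = stats::median(on_c),
    median_onset_ipsi = stats::median(on_i),
    median_difference = stats::median(on_c - on_i),
    fraction_contra_earlier = mean(on_c < on_i),
    z = wt$z, p = wt$p, n = length(common),
    r_diff_vs_log_ratio = safe_cor(on_c - on_i, log(mag_c / mag_i)),
    r_mag_onset_contra = safe_cor(mag_c, on_c),
    r_mag_onset_ipsi = safe_cor(mag_i, on_i),
    differences = data.frame(neuron_id = common, onset_diff_ms = on_c - on_i)
  )
}

# Pearson r, NA when either input is constant (correlation undefined)
safe_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok])
}
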