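#' EMG envelope extraction
#'
#' Band-pass Butterworth filter (20-200 Hz, order 6, zero-phase), full-wave
#' rectification, then a zero-phase low-pass Butterworth (100 Hz, order 6).
#'
#' @param raw numeric vector, one trial's raw EMG.
#' @param fs sampling rate in Hz (> 400).
#' @return Non-negative envelope, same length as `raw`.
#' @export
process_emg <- function(raw, fs = 1000) {
  if (fs <= 400) stop("sampling rate must exceed 400 Hz")
  bp <- signal::butter(6, c(20, 200) / (fs / 2), type = "pass")
  lp <- signal::butter(6, 100 / (fs / 2), type = "low")
  min_len <- 3 * (max(length(bp$a), length(bp$b)) - 1) + 1
  if (length(raw) < 3 * min_len) {
    stop("series shorter than 3 filter lengths")
  }
  band <- signal::filtfilt(bp, raw)
  rect <- abs(band)
  env <- signal::filtfilt(lp, rect)
  pmax(env, 0)
}

#' Epoch statistics and load-sensitivity ANOVA for EMG envelopes
#'
#' Per trial, the envelope is averaged within the baseline and perturbation
#' epochs; per muscle, a two-factor ANOVA (epoch 2 x load 8, Type-II) tests
#' for load sensitivity (significant epoch main effect or interaction).
#'
#' @param env data frame with columns `muscle`, `trial_id`, `load_index`,
#'   `baseline`, `perturbation` (per-trial epoch means of the processed
#'   envelope).
#' @param alpha significance threshold.
#' @return A data frame per muscle: baseline/perturbation RMS, ANOVA
#'   p-values, and a `significant` flag.
#' @export
emg_epoch_stats <- function(env, alpha = 0.05) {
  res <- lapply(split(env, env$muscle), function(d) {
    cells <- table(factor(d$load_index, 0:7))
    if (any(cells == 0)) stop("empty load cells for muscle ", d$muscle[1])
    long <- rbind(
      data.frame(load = factor(d$load_index), epoch = "baseline",
                 value = d$baseline),
      data.frame(load = factor(d$load_index), epoch = "perturbation",
                 value = d$perturbation)
    )
    long$epoch <- factor(long$epoch)
    a <- car::Anova(stats::lm(value ~ epoch * load, data = long), type = 2)
    p <- stats::setNames(a[["Pr(>F)"]], rownames(a))
    data.frame(
      muscle = d$muscle[1],
      rms_baseline = sqrt(mean(d$baseline^2)),
      rms_perturbation = sqrt(mean(d$perturbation^2)),
      p_epoch = p[["epoch"]],
      p_epoch_load = p[["epoch:load"]],
      significant = any(p[c("epoch", "epoch:load")] < alpha, na.rm = TRUE)
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Integrated hand speed after the perturbation
#'
#' Positions are low-pass filtered (3rd-order Butterworth, 10 Hz,
#' zero-phase); hand speed is the magnitude of the differentiated filtered
#' position, integrated (trapezoid) over the window after load onset.
#'
#' @param x,y hand position series (m) at `fs` Hz, aligned so the load is
#'   applied at `onset_idx`.
#' @param fs sampling rate in Hz.
#' @param onset_idx sample index of load onset.
#' @param window_ms integration window in ms after onset.
#' @return Integrated speed (m) over the window.
#' @export
integrated_hand_speed <- function(x, y, fs = 1000, onset_idx = 1,
                                  window_ms = c(0, 300)) {
  lp <- signal::butter(3, 10 / (fs / 2), type = "low")
  xf <- signal::filtfilt(lp, x)
  yf <- signal::filtfilt(lp, y)
  vx <- c(diff(xf), 0) * fs
  vy <- c(diff(yf), 0) * fs
  speed <- sqrt(vx^2 + vy^2)
  i0 <- onset_idx + round(window_ms[1] * fs / 1000)
  i1 <- onset_idx + round(window_ms[2] * fs / 1000)
  if (i0 < 1 || i1 > length(speed)) stop("window outside the recording")
  idx <- i0:i1
  sum((speed[idx[-length(idx)]] + speed[idx[-1]]) / 2) / fs
}

#' Perturbed-to-unperturbed hand motion ratio
#'
#' @param speed_perturbed,speed_unperturbed integrated hand speeds per trial
#'   for the loaded and unloaded hand.
#' @return Ratio of the mean integrated speeds.
#' @export
hand_speed_ratio <- function(speed_perturbed, speed_unperturbed) {
  mean(speed_perturbed) / mean(speed_unperturbed)
}
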