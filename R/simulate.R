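#' Configuration for the synthetic session generator
#'
#' The generator emulates the study conditions of a single-hemisphere
#' perturbation session: ~100 neurons, both contexts over the eight canonical
#' loads with at least 10 trials per condition, 1 ms spike resolution, planar
#' torque tuning with an axially bimodal preferred-load distribution, a
#' contra:ipsi response-magnitude ratio near 2, an ipsilateral onset lag near
#' 10 ms, and latent activity confined to low-dimensional subspaces of
#' configurable mutual alignment.
#'
#' @param n_neurons number of simulated neurons.
#' @param n_trials_per_condition trials per (context, load) cell.
#' @param d_latent latent dimensions per context.
#' @param alignment mean squared cosine of the principal angles between the
#'   two context subspaces, in `[0, 1]` (0 = orthogonal, 1 = identical).
#' @param contra_gain_ratio ratio of contralateral to ipsilateral response
#'   magnitude.
#' @param onset_ms named numeric `c(contra =, ipsi =)` response onsets in ms
#'   after load application.
#' @param bimodal_axis_deg major axis of the preferred-load distribution in
#'   joint-torque space.
#' @param concentration von Mises concentration of the axial preferred-load
#'   mixture (0 = uniform).
#' @param baseline_rate_hz baseline firing rate.
#' @param magnitude_hz_per_nm target median contralateral planar-fit
#'   magnitude (calibrated on the perturbation-epoch mean).
#' @param profile_rise_ms rise time of the response transient.
#' @param profile_decay_ms decay time from the transient peak to the
#'   sustained plateau.
#' @param profile_peak transient peak as a multiple of the sustained
#'   plateau (perturbation responses burst before settling).
#' @param untuned_gain magnitude of each neuron's load-independent
#'   (condition-independent) perturbation response, as a fraction of its
#'   tuned response; keeps suppressed lobes away from the zero-rate floor,
#'   as in cortical perturbation responses.
#' @param seed integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_neurons = 100, n_trials_per_condition = 10,
                       d_latent = 3, alignment = 0, contra_gain_ratio = 2,
                       onset_ms = c(contra = 25, ipsi = 35),
                       bimodal_axis_deg = 135, concentration = 2,
                       baseline_rate_hz = 10, magnitude_hz_per_nm = 30,
                       profile_rise_ms = 15, profile_decay_ms = 100,
                       profile_peak = 3, untuned_gain = 0.75, seed = 1L) {
  cfg <- structure(
    list(n_neurons = as.integer(n_neurons),
         n_trials_per_condition = as.integer(n_trials_per_condition),
         d_latent = as.integer(d_latent),
         alignment = alignment,
         contra_gain_ratio = contra_gain_ratio,
         onset_ms = onset_ms,
         bimodal_axis_deg = bimodal_axis_deg,
         concentration = concentration,
         baseline_rate_hz = baseline_rate_hz,
         magnitude_hz_per_nm = magnitude_hz_per_nm,
         profile_rise_ms = profile_rise_ms,
         profile_decay_ms = profile_decay_ms,
         profile_peak = profile_peak,
         untuned_gain = untuned_gain,
         seed = as.integer(seed)),
    class = "sim_config"
  )
  if (cfg$alignment < 0 || cfg$alignment > 1) {
    stop("alignment must lie in [0, 1]")
  }
  if (2L * cfg$d_latent > cfg$n_neurons) {
    stop("2 * d_latent must not exceed n_neurons")
  }
  if (cfg$baseline_rate_hz < 0 || cfg$concentration < 0) {
    stop("rates and concentration must be non-negative")
  }
  if (!all(c("contra", "ipsi") %in% names(cfg$onset_ms))) {
    stop("onset_ms needs named entries 'contra' and 'ipsi'")
  }
  cfg
}

#' Sample preferred-load axes from an axial von Mises distribution
#'
#' Axial (180-degree symmetric) angles: the doubled angles follow a von
#' Mises distribution centred on `2 * axis_deg` with concentration kappa, so
#' the sample's bimodal Rayleigh statistic converges to the von Mises mean
#' resultant `I1(kappa) / I0(kappa)`. Each draw lands on `axis_deg` or
#' `axis_deg + 180` with equal probability.
#'
#' @param n number of angles.
#' @param axis_deg major axis in degrees.
#' @param concentration von Mises kappa of the doubled angles (0 gives the
#'   uniform distribution).
#' @param seed optional integer seed.
#' @return `n` angles in degrees in `[0, 360)`.
#' @export
sample_preferred_axes <- function(n, axis_deg = 135, concentration = 2,
                                  seed = NULL) {
  stopifnot(n >= 1, concentration >= 0)
  if (!is.null(seed)) set.seed(seed)
  flip <- 180 * (stats::runif(n) < 0.5)
  (axis_deg + rvonmises(n, concentration) / 2 + flip) %% 360
}

# von Mises deviates (degrees, mean 0) by Best & Fisher (1979) rejection.
rvonmises <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    theta <- sign(u3 - 0.5) * acos(f)
    keep <- theta[ok]
    if (length(keep)) {
      out[(got + 1):min(n, got + length(keep))] <-
        keep[seq_len(min(length(keep), n - got))]
      got <- got + min(length(keep), n - got)
    }
  }
  out * 180 / pi
}

#' Alignment between two orthonormal bases
#'
#' Mean squared cosine of the principal angles between the column spans:
#' 1 for identical spans, 0 for orthogonal spans.
#'
#' @param U_a,U_b matrices with the same number of rows and orthonormal
#'   columns.
#' @return Scalar in `[0, 1]`.
#' @export
alignment_of_bases <- function(U_a, U_b) {
  check_orthonormal(U_a, "U_a")
  check_orthonormal(U_b, "U_b")
  stopifnot(nrow(U_a) == nrow(U_b))
  s <- svd(crossprod(U_a, U_b))$d
  mean(pmin(s, 1)^2)
}

check_orthonormal <- function(U, name, tol = 1e-8) {
  g <- crossprod(U)
  if (max(abs(g - diag(ncol(U)))) > tol) {
    stop(name, " does not have orthonormal columns")
  }
  invisible(TRUE)
}

# Two orthonormal bases with exactly the requested alignment: take a random
# 2d-frame [W1 W2] and mix the halves column-wise by the angle theta with
# cos^2(theta) = alignment.
make_aligned_bases <- function(n, d, alignment) {
  W <- qr.Q(qr(matrix(stats::rnorm(n * 2 * d), n, 2 * d)))
  W1 <- W[, 1:d, drop = FALSE]
  W2 <- W[, (d + 1):(2 * d), drop = FALSE]
  ct <- sqrt(alignment)
  st <- sqrt(1 - alignment)
  list(U_a = W1, U_b = W1 * ct + W2 * st)
}

#' Simulate a two-context session with known ground truth
#'
#' Latent activity per condition is a planar amplitude (latent tuning vector
#' dotted with the applied torque) times a delayed ramp-and-hold temporal
#' profile; neuron rates are baseline plus the context basis times the
#' latents, rectified at zero and scaled so contralateral planar magnitudes
#' exceed ipsilateral ones by `contra_gain_ratio`. Spikes are an inhomogeneous
#' Poisson process at 1 ms resolution.
#'
#' @param config a [sim_config()].
#' @return A list with elements `session` (a validated [session()]) and
#'   `ground_truth` (bases `U_contra`/`U_ipsi`, per-neuron true preferred
#'   angles and gains per context, true onsets, the requested alignment).
#' @export
simulate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  loads <- canonical_load_set()
  n <- config$n_neurons
  d <- config$d_latent
  ctxs <- c("contra", "ipsi")

  bases <- make_aligned_bases(n, d, config$alignment)
  U <- list(contra = bases$U_a, ipsi = bases$U_b)

  # latent torque-tuning directions shared across contexts; per-dimension
  # gains taper so the latent spectrum is ordered
  phi <- sample_preferred_axes(d, config$bimodal_axis_deg, config$concentration)
  V <- cbind(cos(phi * pi / 180), sin(phi * pi / 180))      # d x 2
  g <- seq(1, 0.6, length.out = d)

  tau <- as.matrix(loads[, c("shoulder_torque_nm", "elbow_torque_nm")])  # 8 x 2
  B0 <- list()      # neurons x 2 unit-scale tuning planes (Hz/Nm at scale 1)
  scale_ctx <- c(contra = NA_real_, ipsi = NA_real_)
  mag_target <- c(contra = config$magnitude_hz_per_nm,
                  ipsi = config$magnitude_hz_per_nm / config$contra_gain_ratio)
  # calibrate so the perturbation-epoch mean response matches the target
  # median planar magnitude (the profile's epoch mean differs from 1)
  prof_epoch_mean <- vapply(ctxs, function(ctx) {
    p <- response_profile(1300, 0, config$onset_ms[[ctx]],
                          config$profile_rise_ms, config$profile_decay_ms,
                          config$profile_peak)
    mean(p[1:300])
  }, numeric(1))
  for (ctx in ctxs) {
    B0[[ctx]] <- U[[ctx]] %*% (g * V)
    med <- stats::median(sqrt(rowSums(B0[[ctx]]^2)))
    scale_ctx[ctx] <- mag_target[ctx] / (med * prof_epoch_mean[[ctx]])
  }

  n_tr <- config$n_trials_per_condition
  trial_rows <- list()
  spike_rows <- list()
  neuron_ids <- sprintf("n%03d", seq_len(n))
  trial_id <- 0L
  for (ctx in ctxs) {
    # tuned response per load plus a load-independent evoked component
    tuned <- B0[[ctx]] %*% t(tau)                    # neurons x 8
    untuned <- config$untuned_gain * sqrt(rowSums(B0[[ctx]]^2)) %o%
      sqrt(rowSums(tau^2))
    amp <- scale_ctx[ctx] * (tuned + untuned)        # Hz at plateau
    onset <- config$onset_ms[[ctx]]
    for (c_idx in 1:8) {
      for (k in seq_len(n_tr)) {
        trial_id <- trial_id + 1L
        perturb <- sample(seq(500, 1000, by = 10), 1)
        t_end <- perturb + 1300
        prof <- response_profile(t_end, perturb, onset,
                                 config$profile_rise_ms,
                                 config$profile_decay_ms,
                                 config$profile_peak)
        lam <- pmax(config$baseline_rate_hz +
                      outer(amp[, c_idx], prof), 0)     # neurons x t_end, Hz
        counts <- matrix(stats::rpois(length(lam), lam / 1000),
                         nrow = n)
        hit <- which(counts > 0L, arr.ind = TRUE)
        if (nrow(hit)) {
          reps <- counts[hit]
          spike_rows[[trial_id]] <- data.frame(
            neuron_id = rep(neuron_ids[hit[, 1]], reps),
            trial_id = trial_id,
            spike_time_ms = rep(hit[, 2] - 1L, reps)
          )
        }
        trial_rows[[trial_id]] <- data.frame(
          trial_id = trial_id, context = ctx,
          shoulder_torque_nm = tau[c_idx, 1], elbow_torque_nm = tau[c_idx, 2],
          perturb_time_ms = perturb, trial_end_ms = t_end
        )
      }
    }
  }
  trials <- do.call(rbind, trial_rows)
  spikes <- do.call(rbind, spike_rows)
  if (is.null(spikes)) {
    spikes <- data.frame(neuron_id = character(), trial_id = integer(),
                         spike_time_ms = numeric())
  }

  truth <- list(
    U_contra = U$contra,
    U_ipsi = U$ipsi,
    alignment = config$alignment,
    latent_axes_deg = phi,
    onset_ms = config$onset_ms,
    preferred_angle_deg = lapply(B0, function(b) load_angle(b[, 1], b[, 2])),
    gain_hz_per_nm = list(
      contra = scale_ctx["contra"] * sqrt(rowSums(B0$contra^2)),
      ipsi = scale_ctx["ipsi"] * sqrt(rowSums(B0$ipsi^2))
    ),
    neuron_ids = neuron_ids,
    config = config
  )
  list(session = session(trials, spikes), ground_truth = truth)
}

# transient-plus-plateau response profile over a trial of t_end ms (1 ms
# bins): zero before perturb + onset, linear rise to `peak` over rise_ms, a
# linear decay back to the sustained plateau of 1 over decay_ms, then held
# until the trial ends
response_profile <- function(t_end, perturb, onset, rise_ms, decay_ms, peak) {
  t <- seq_len(t_end) - 1
  rel <- t - (perturb + onset)
  p <- numeric(t_end)
  rising <- rel >= 0 & rel < rise_ms
  p[rising] <- peak * rel[rising] / rise_ms
  decaying <- rel >= rise_ms & rel < rise_ms + decay_ms
  p[decaying] <- peak - (peak - 1) * (rel[decaying] - rise_ms) / decay_ms
  p[rel >= rise_ms + decay_ms] <- 1
  p
}
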