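#' Per-neuron load-sensitivity classification (three-way ANOVA)
#'
#' For each neuron, a fully crossed three-factor ANOVA (epoch 2 x context 2 x
#' load 8, Type-II sums of squares) is applied to the per-trial epoch mean
#' rates (baseline and perturbation). A neuron is load sensitive when the
#' epoch main effect or any interaction involving epoch has `p < alpha`.
#'
#' @param em per-trial epoch means from [epoch_means()].
#' @param alpha significance threshold.
#' @return A data frame with one row per neuron: `load_sensitive` plus the
#'   p-values for the epoch main effect and every epoch-involving
#'   interaction.
#' @export
load_sensitivity_anova <- function(em, alpha = 0.05) {
  check_full_design(em)
  long <- rbind(
    data.frame(em[c("neuron_id", "context", "load_index", "trial_id")],
               epoch = "baseline", rate = em$baseline),
    data.frame(em[c("neuron_id", "context", "load_index", "trial_id")],
               epoch = "perturbation", rate = em$perturbation)
  )
  long$epoch <- factor(long$epoch)
  long$context <- factor(long$context)
  long$load <- factor(long$load_index)
  res <- lapply(split(long, long$neuron_id), function(d) {
    fit <- stats::lm(rate ~ epoch * context * load, data = d)
    a <- car::Anova(fit, type = 2)
    p <- stats::setNames(a[["Pr(>F)"]], rownames(a))
    keep <- c("epoch", "epoch:context", "epoch:load", "epoch:context:load")
    p <- p[keep]
    data.frame(neuron_id = d$neuron_id[1],
               p_epoch = p[["epoch"]],
               p_epoch_context = p[["epoch:context"]],
               p_epoch_load = p[["epoch:load"]],
               p_epoch_context_load = p[["epoch:context:load"]],
               load_sensitive = any(p < alpha, na.rm = TRUE))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

check_full_design <- function(em) {
  cells <- table(factor(em$context, c("contra", "ipsi")),
                 factor(em$load_index, 0:7))
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty factor cells: ",
         paste(sprintf("(%s, load %s)", rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]]), collapse = ", "))
  }
  invisible(TRUE)
}

#' Planar preferred-load fit for one neuron, context, and epoch
#'
#' Least-squares fit `rate = offset + b_s * tau_shoulder + b_e * tau_elbow`
#' to per-trial epoch-mean rates (mean-centred first) over the eight load
#' combinations. The preferred load is `atan2(b_e, b_s)` and the magnitude
#' `sqrt(b_s^2 + b_e^2)` in Hz/Nm; the p-value is the overall regression
#' F-test.
#'
#' @param rate per-trial epoch-mean rates (Hz).
#' @param shoulder,elbow applied torques (Nm) matching `rate`.
#' @return A one-row data frame: `offset`, `b_shoulder`, `b_elbow`,
#'   `preferred_angle_deg` in `[0, 360)`, `magnitude_hz_per_nm`, `p_value`.
#' @export
fit_plane <- function(rate, shoulder, elbow) {
  stopifnot(length(rate) == length(shoulder), length(rate) == length(elbow))
  X <- cbind(1, shoulder, elbow)
  if (qr(X)$rank < 3) stop("rank-deficient torque design")
  y <- rate - mean(rate)
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  df2 <- length(y) - 3
  if (df2 <= 0) stop("need more observations than coefficients")
  if (tss <= 0) {
    p <- 1
  } else if (rss < .Machine$double.eps * tss) {
    p <- 0
  } else {
    f <- ((tss - rss) / 2) / (rss / df2)
    p <- stats::pf(f, 2, df2, lower.tail = FALSE)
  }
  data.frame(
    offset = b[[1]] + mean(rate),
    b_shoulder = b[[2]], b_elbow = b[[3]],
    preferred_angle_deg = load_angle(b[[2]], b[[3]]),
    magnitude_hz_per_nm = sqrt(b[[2]]^2 + b[[3]]^2),
    p_value = p
  )
}

#' Planar fits for every neuron, context, and epoch
#'
#' @param em per-trial epoch means from [epoch_means()].
#' @param epochs which epoch columns to fit (`"perturbation"`,
#'   `"steady"`).
#' @return A data frame of [fit_plane()] rows keyed by `neuron_id`,
#'   `context`, `epoch`.
#' @export
fit_planes <- function(em, epochs = c("perturbation", "steady")) {
  loads <- canonical_load_set()
  sh <- loads$shoulder_torque_nm[em$load_index + 1L]
  el <- loads$elbow_torque_nm[em$load_index + 1L]
  out <- list()
  for (ep in epochs) {
    rate <- em[[ep]]
    grp <- split(seq_len(nrow(em)), list(em$neuron_id, em$context), drop = TRUE)
    for (g in grp) {
      fit <- fit_plane(rate[g], sh[g], el[g])
      out[[length(out) + 1L]] <- cbind(
        data.frame(neuron_id = em$neuron_id[g[1]], context = em$context[g[1]],
                   epoch = ep),
        fit
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rayleigh statistics of an angular sample
#'
#' The unimodal R is the mean resultant length of unit vectors at the given
#' angles; the bimodal (axial) variant doubles the angles first, detecting
#' 180-degree-symmetric structure. The major axis is the argument of the
#' resultant (halved for the bimodal statistic).
#'
#' @param angles_deg angles in degrees.
#' @param mode `"unimodal"` or `"bimodal"`.
#' @return A list with `R` in `[0, 1]` and `axis_deg`.
#' @export
rayleigh_stats <- function(angles_deg, mode = c("unimodal", "bimodal")) {
  mode <- match.arg(mode)
  stopifnot(length(angles_deg) >= 1)
  mult <- if (mode == "bimodal") 2 else 1
  z <- exp(1i * mult * angles_deg * pi / 180)
  m <- mean(z)
  axis <- (Arg(m) * 180 / pi / mult) %% (360 / mult)
  list(R = Mod(m), axis_deg = axis)
}

#' Bootstrap p-value for a Rayleigh statistic against uniform angles
#'
#' Draws `n_boot` uniform samples of the same size and reports the fraction
#' whose R statistic meets or exceeds the observed one.
#'
#' @param angles_deg observed angles in degrees.
#' @param mode `"unimodal"` or `"bimodal"`.
#' @param n_boot number of uniform bootstrap samples.
#' @param seed optional integer seed.
#' @return A list with `R`, `axis_deg`, `p`, `n_boot`, `seed`.
#' @export
rayleigh_bootstrap_p <- function(angles_deg, mode = c("unimodal", "bimodal"),
                                 n_boot = 1000, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(angles_deg) >= 2)
  if (!is.null(seed)) set.seed(seed)
  obs <- rayleigh_stats(angles_deg, mode)
  n <- length(angles_deg)
  mult <- if (mode == "bimodal") 2 else 1
  u <- matrix(stats::runif(n * n_boot, 0, 2 * pi * mult), n, n_boot)
  null_R <- Mod(colMeans(exp(1i * u)))
  list(R = obs$R, axis_deg = obs$axis_deg, p = mean(null_R >= obs$R),
       n_boot = n_boot, seed = seed)
}

#' Change in preferred load between two sets of planar fits
#'
#' Signed circular differences (`a - b`) in `(-180, 180]` over the neurons
#' present in both fit tables, with the unimodal Rayleigh statistic and its
#' uniform bootstrap p-value.
#'
#' @param fits_a,fits_b data frames with `neuron_id` and
#'   `preferred_angle_deg` (e.g. subsets of [fit_planes()] output).
#' @param n_boot,seed bootstrap controls for the Rayleigh p-value.
#' @return A list: per-neuron `differences` data frame, `R`, `axis_deg`,
#'   `p`.
#' @export
tuning_difference <- function(fits_a, fits_b, n_boot = 1000, seed = NULL) {
  common <- intersect(fits_a$neuron_id, fits_b$neuron_id)
  if (!length(common)) stop("no common neurons between the two fit sets")
  a <- fits_a$preferred_angle_deg[match(common, fits_a$neuron_id)]
  b <- fits_b$preferred_angle_deg[match(common, fits_b$neuron_id)]
  d <- circular_difference(a, b)
  stat <- rayleigh_bootstrap_p(d, "unimodal", n_boot = n_boot, seed = seed)
  axis <- rayleigh_stats(d, "unimodal")$axis_deg
  axis <- ((axis + 180) %% 360) - 180
  list(
    differences = data.frame(neuron_id = common, angle_diff_deg = d),
    R = stat$R, axis_deg = axis, p = stat$p, n_boot = n_boot, seed = seed
  )
}

#' Signed circular difference in (-180, 180]
#' @param a,b angles in degrees.
#' @return `a - b` wrapped to `(-180, 180]`.
#' @export
circular_difference <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

#' Contrast of planar-fit magnitudes between contexts
#'
#' Pairs each neuron's contralateral and ipsilateral planar-fit magnitudes,
#' reporting the per-context medians, the Wilcoxon signed-rank statistic
#' (normal approximation z and p) on the differences, and the fraction of
#' neurons with the contralateral magnitude larger.
#'
#' @param fits_contra,fits_ipsi data frames with `neuron_id` and
#'   `magnitude_hz_per_nm`.
#' @return A list of summary statistics plus the per-neuron difference
#'   table.
#' @export
magnitude_contrast <- function(fits_contra, fits_ipsi) {
  common <- intersect(fits_contra$neuron_id, fits_ipsi$neuron_id)
  if (length(common) < 5) stop("need at least 5 paired neurons")
  mc <- fits_contra$magnitude_hz_per_nm[match(common, fits_contra$neuron_id)]
  mi <- fits_ipsi$magnitude_hz_per_nm[match(common, fits_ipsi$neuron_id)]
  wt <- signed_rank(mc - mi)
  list(
    median_contra = stats::median(mc),
    median_ipsi = stats::median(mi),
    fraction_contra_larger = mean(mc > mi) + 0.5 * mean(mc == mi),
    z = wt$z, p = wt$p, n = length(common),
    differences = data.frame(neuron_id = common, magnitude_diff = mc - mi)
  )
}

# Wilcoxon signed-rank with normal approximation (average ranks for ties,
# zeros dropped); returns signed z and two-sided p
signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(z = 0, p = 1))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w_pos - mu) / sqrt(sigma2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
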