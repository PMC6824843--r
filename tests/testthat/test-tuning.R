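make_load_obs <- function(f, n_rep = 4, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loads <- canonical_load_set()
  sh <- rep(loads$shoulder_torque_nm, n_rep)
  el <- rep(loads$elbow_torque_nm, n_rep)
  rate <- f(sh, el) + stats::rnorm(length(sh), 0, noise_sd)
  list(rate = rate, sh = sh, el = el)
}

test_that("planar fits are exact on noiseless planar rates", {
  obs <- make_load_obs(function(s, e) 10 + 5 * s + 3 * e)
  fit <- fit_plane(obs$rate, obs$sh, obs$el)
  expect_equal(fit$b_shoulder, 5, tolerance = 1e-10)
  expect_equal(fit$b_elbow, 3, tolerance = 1e-10)
  expect_equal(fit$preferred_angle_deg, atan2(3, 5) * 180 / pi,
               tolerance = 1e-8)
  expect_equal(fit$magnitude_hz_per_nm, sqrt(34), tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-12)
  expect_equal(fit$offset, 10, tolerance = 1e-10)

  expect_error(fit_plane(rep(1, 8), rep(0.2, 8), rep(0, 8)), "rank")
})

test_that("null rates give near-zero magnitude and uniform-ish p-values", {
  set.seed(31)
  ps <- replicate(200, {
    obs <- make_load_obs(function(s, e) rep(8, length(s)), noise_sd = 2)
    fit_plane(obs$rate, obs$sh, obs$el)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 1e-3)
  obs <- make_load_obs(function(s, e) rep(8, length(s)), noise_sd = 2,
                       seed = 5)
  expect_lt(fit_plane(obs$rate, obs$sh, obs$el)$magnitude_hz_per_nm, 15)
})

test_that("rayleigh statistics handle degenerate, axial, and symmetric sets", {
  expect_equal(rayleigh_stats(rep(135, 50), "unimodal")$R, 1)
  expect_equal(rayleigh_stats(rep(135, 50), "unimodal")$axis_deg, 135)

  pair <- c(0, 180)
  expect_equal(rayleigh_stats(pair, "unimodal")$R, 0, tolerance = 1e-12)
  expect_equal(rayleigh_stats(pair, "bimodal")$R, 1, tolerance = 1e-12)

  quad <- c(0, 90, 180, 270)
  expect_equal(rayleigh_stats(quad, "unimodal")$R, 0, tolerance = 1e-12)
  expect_equal(rayleigh_stats(quad, "bimodal")$R, 0, tolerance = 1e-12)
})

test_that("rayleigh R is rotation invariant and the axis tracks the rotation", {
  set.seed(8)
  ang <- sample_preferred_axes(60, 40, 3)
  base <- rayleigh_stats(ang, "bimodal")
  rot <- rayleigh_stats((ang + 25) %% 360, "bimodal")
  expect_equal(rot$R, base$R, tolerance = 1e-12)
  expect_equal((rot$axis_deg - base$axis_deg) %% 180, 25, tolerance = 1e-8)
})

test_that("rayleigh bootstrap p is seeded, order-invariant, and degenerate at R=1", {
  ang <- rep(90, 50)
  expect_equal(rayleigh_bootstrap_p(ang, "unimodal", seed = 1)$p, 0)

  set.seed(9)
  ang <- stats::runif(40, 0, 360)
  p1 <- rayleigh_bootstrap_p(ang, "bimodal", n_boot = 300, seed = 4)
  p2 <- rayleigh_bootstrap_p(sample(ang), "bimodal", n_boot = 300, seed = 4)
  expect_identical(p1$p, p2$p)
})

test_that("three-way ANOVA flags responsive neurons and spares flat ones", {
  em <- demo_epoch_means()
  # flat neuron: copy baseline into perturbation
  flat <- em[em$neuron_id == "n001", ]
  flat$perturbation <- flat$baseline
  res_flat <- load_sensitivity_anova(flat)
  expect_false(res_flat$load_sensitive)
  expect_gt(res_flat$p_epoch, 0.99)

  res <- load_sensitivity_anova(em)
  expect_equal(nrow(res), 30)
  expect_gt(mean(res$load_sensitive), 0.5)

  # a neuron responding on a single load is caught via the epoch x load
  # interaction
  set.seed(21)
  hits <- replicate(20, {
    one <- em[em$neuron_id == "n001", ]
    one$baseline <- stats::rnorm(nrow(one), 10, 1.5)
    one$perturbation <- stats::rnorm(nrow(one), 10, 1.5) +
      20 * (one$load_index == 3)
    r <- load_sensitivity_anova(one)
    r$load_sensitive && r$p_epoch_load < 0.05
  })
  expect_gte(mean(hits), 0.95)

  expect_error(load_sensitivity_anova(em[em$load_index != 5, ]), "load 5")
})

test_that("tuning differences recover identity and stability across epochs", {
  fits <- fit_planes(demo_epoch_means())
  pert_c <- fits[fits$context == "contra" & fits$epoch == "perturbation", ]
  td <- tuning_difference(pert_c, pert_c, n_boot = 200, seed = 2)
  expect_equal(td$differences$angle_diff_deg, rep(0, nrow(td$differences)))
  expect_equal(td$R, 1)
  expect_equal(td$axis_deg, 0)

  # simulated tuning is stable across epochs: axis near zero, tight
  steady_c <- fits[fits$context == "contra" & fits$epoch == "steady", ]
  sig <- intersect(pert_c$neuron_id[pert_c$p_value < 0.05],
                   steady_c$neuron_id[steady_c$p_value < 0.05])
  td2 <- tuning_difference(pert_c[pert_c$neuron_id %in% sig, ],
                           steady_c[steady_c$neuron_id %in% sig, ],
                           n_boot = 300, seed = 2)
  expect_lt(abs(td2$axis_deg), 10)
  expect_lt(td2$p, 0.01)

  expect_error(tuning_difference(pert_c[0, ], steady_c), "common")
})

test_that("magnitude contrast is null for identical fits and needs 5 neurons", {
  fits <- fit_planes(demo_epoch_means())
  pert_c <- fits[fits$context == "contra" & fits$epoch == "perturbation", ]
  mc <- magnitude_contrast(pert_c, pert_c)
  expect_equal(mc$z, 0)
  expect_equal(mc$fraction_contra_larger, 0.5)   # all ties split evenly
  expect_error(magnitude_contrast(pert_c[1:3, ], pert_c[1:3, ]), "5")
})

test_that("circular differences wrap into (-180, 180]", {
  expect_equal(circular_difference(10, 350), 20)
  expect_equal(circular_difference(350, 10), -20)
  expect_equal(circular_difference(200, 20), 180)
  expect_equal(circular_difference(20, 200), 180)
})
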