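test_that("simulation is deterministic under a fixed config and seed", {
  cfg <- sim_config(n_neurons = 8, n_trials_per_condition = 2, seed = 17)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$session$trials, b$session$trials)
  expect_identical(a$session$spikes, b$session$spikes)
  expect_identical(a$ground_truth$U_contra, b$ground_truth$U_contra)

  c2 <- simulate_session(sim_config(n_neurons = 8, n_trials_per_condition = 2,
                                    seed = 18))
  expect_false(identical(a$session$spikes, c2$session$spikes))
})

test_that("configs violating invariants are refused before simulation", {
  expect_error(sim_config(alignment = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(n_neurons = 4, d_latent = 3), "d_latent")
  expect_error(sim_config(baseline_rate_hz = -1), "non-negative")
  expect_error(sim_config(onset_ms = c(20, 30)), "named")
})

test_that("ground-truth bases are orthonormal with the requested alignment", {
  for (a in c(0, 0.25, 0.5, 0.75, 1)) {
    sim <- simulate_session(sim_config(n_neurons = 20, d_latent = 3,
                                       n_trials_per_condition = 2,
                                       alignment = a, seed = 3))
    gt <- sim$ground_truth
    expect_lt(max(abs(crossprod(gt$U_contra) - diag(3))), 1e-10)
    expect_lt(max(abs(crossprod(gt$U_ipsi) - diag(3))), 1e-10)
    expect_equal(alignment_of_bases(gt$U_contra, gt$U_ipsi), a,
                 tolerance = 1e-8)
    if (a == 0) {
      # principal angles all 90 degrees by construction
      cosines <- svd(crossprod(gt$U_contra, gt$U_ipsi))$d
      expect_lt(max(cosines), 1e-8)
    }
  }
})

test_that("alignment_of_bases handles identity, orthogonality, and half overlap", {
  U <- diag(4)
  expect_equal(alignment_of_bases(U[, 1:2], U[, 1:2]), 1)
  expect_equal(alignment_of_bases(U[, 1:2], U[, 3:4]), 0)
  # one shared axis, one orthogonal: principal angles {0, 90} -> 0.5
  expect_equal(alignment_of_bases(U[, 1:2], U[, c(1, 3)]), 0.5)
  expect_error(alignment_of_bases(cbind(c(1, 1, 0, 0)), U[, 1:2]),
               "orthonormal")
})

test_that("preferred-axis sampling spans uniform to degenerate limits", {
  n <- 2000
  flat <- sample_preferred_axes(n, 135, 0, seed = 2)
  expect_lt(rayleigh_stats(flat, "bimodal")$R, 3 / sqrt(n))
  expect_true(all(flat >= 0 & flat < 360))

  tight <- sample_preferred_axes(500, 135, 5000, seed = 2)
  d <- pmin(abs(circular_difference(tight, 135)),
            abs(circular_difference(tight, 315)))
  expect_lt(max(d), 5)

  # concentration 2: axial resultant matches the Bessel ratio I1(2)/I0(2)
  ang <- sample_preferred_axes(n, 135, 2, seed = 7)
  expect_equal(rayleigh_stats(ang, "bimodal")$R,
               besselI(2, 1) / besselI(2, 0), tolerance = 0.02)
  expect_equal(rayleigh_stats(ang, "bimodal")$axis_deg %% 180, 135,
               tolerance = 3)
})

test_that("zero-gain sessions emit baseline Poisson spiking", {
  cfg <- sim_config(n_neurons = 4, n_trials_per_condition = 25, d_latent = 1,
                    magnitude_hz_per_nm = 0, baseline_rate_hz = 20, seed = 9)
  sim <- simulate_session(cfg)
  s <- sim$session
  # count spikes in a fixed 1 s window per neuron x trial
  counts <- matrix(0, 4, nrow(s$trials))
  sp <- s$spikes
  start <- s$trials$perturb_time_ms[sp$trial_id]
  in_win <- sp$spike_time_ms >= start & sp$spike_time_ms < start + 1000
  tab <- table(factor(sp$neuron_id[in_win], sort(unique(sp$neuron_id))),
               factor(sp$trial_id[in_win], s$trials$trial_id))
  for (ni in 1:4) {
    x <- as.numeric(tab[ni, ])
    expect_equal(mean(x), 20, tolerance = 1.5)
    expect_gt(stats::var(x) / mean(x), 0.8)
    expect_lt(stats::var(x) / mean(x), 1.2)
  }
})

test_that("identical contexts produce matching trial-averaged responses", {
  cfg <- sim_config(n_neurons = 12, n_trials_per_condition = 8, alignment = 1,
                    contra_gain_ratio = 1,
                    onset_ms = c(contra = 25, ipsi = 25), seed = 6)
  sim <- simulate_session(cfg)
  rs <- smooth_spike_trains(sim$session)
  em <- epoch_means(rs)
  agg <- stats::aggregate(perturbation ~ neuron_id + load_index + context,
                          em, mean)
  wide <- stats::reshape(agg, direction = "wide",
                         idvar = c("neuron_id", "load_index"),
                         timevar = "context")
  d <- wide$perturbation.contra - wide$perturbation.ipsi
  # paired difference consistent with zero at Poisson trial noise
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * se + 0.5)
})

test_that("rates are rectified and spike times stay inside their trials", {
  sim <- demo_sim()
  s <- sim$session
  expect_true(all(s$spikes$spike_time_ms >= 0))
  end <- s$trials$trial_end_ms[match(s$spikes$trial_id, s$trials$trial_id)]
  expect_true(all(s$spikes$spike_time_ms <= end))
  expect_true(all(demo_rates()$rates$contra[[1]] >= 0))
})
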