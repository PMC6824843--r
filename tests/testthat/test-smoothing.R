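test_that("post-spike kernel is normalized, causal, and peaks near 3 ms", {
  k <- postspike_kernel()
  expect_equal(sum(k$weights) * k$dt_ms, 1, tolerance = 1e-9)
  expect_equal(k$lag0, 1L)          # no weight before the spike
  expect_equal(k$times_ms[1], 0)
  expect_equal(k$weights[1], 0)     # k(0) = 0: rises from zero

  # peak location against a numeric maximization of the continuous form
  f <- function(t) (1 - exp(-t / 1)) * exp(-t / 20)
  t_star <- stats::optimize(f, c(0, 50), maximum = TRUE)$maximum
  expect_equal(t_star, log(21), tolerance = 1e-4)
  fine <- postspike_kernel(dt_ms = 0.001)
  expect_equal(fine$times_ms[which.max(fine$weights)], t_star,
               tolerance = 1e-3)

  expect_error(postspike_kernel(rise_ms = 0), "positive")
  expect_error(postspike_kernel(rise_ms = 30, fall_ms = 20), "smaller")
})

test_that("gaussian kernel is symmetric and unit-area", {
  g <- gaussian_kernel(20)
  expect_equal(sum(g$weights) * g$dt_ms, 1, tolerance = 1e-9)
  expect_equal(g$weights, rev(g$weights))
  expect_equal(g$times_ms[g$lag0], 0)
})

test_that("smoothing reproduces the impulse response and is causal and linear", {
  k <- postspike_kernel()
  sp <- function(times) data.frame(neuron_id = "a", trial_id = 1L,
                                   spike_time_ms = times)
  r <- motorload:::trial_rates(sp(100), "a", 1000, k)
  expect_equal(as.numeric(r[1, 101:(100 + length(k$weights))]),
               k$weights * 1000, tolerance = 1e-9)
  expect_true(all(r[1, 1:100] == 0))   # nothing before the spike

  # causality: deleting spikes after t leaves [0, t] unchanged
  r_all <- motorload:::trial_rates(sp(c(100, 300, 700)), "a", 1000, k)
  r_cut <- motorload:::trial_rates(sp(c(100, 300)), "a", 1000, k)
  expect_equal(r_all[1, 1:500], r_cut[1, 1:500], tolerance = 1e-9)

  # linearity: superposed trains sum
  r1 <- motorload:::trial_rates(sp(100), "a", 1000, k)
  r2 <- motorload:::trial_rates(sp(400), "a", 1000, k)
  r12 <- motorload:::trial_rates(sp(c(100, 400)), "a", 1000, k)
  expect_equal(as.numeric(r12), as.numeric(r1 + r2), tolerance = 1e-9)
})

test_that("a long homogeneous Poisson train smooths to its true rate", {
  set.seed(7)
  n_ms <- 10000
  counts <- stats::rpois(n_ms, 50 / 1000)
  times <- rep(seq_len(n_ms) - 1, counts)
  r <- motorload:::trial_rates(
    data.frame(neuron_id = "a", trial_id = 1L, spike_time_ms = times),
    "a", n_ms, postspike_kernel()
  )
  expect_equal(mean(r[1, 500:n_ms]), 50, tolerance = 3)
})

test_that("epoch means recover constants, steps, and ramps", {
  # constant 10 Hz
  rs <- manual_rate_series(1, 2, function(ni, ctx, ci, t) rep(10, length(t)),
                           steady_hz = 10)
  em <- epoch_means(rs)
  expect_equal(unique(em$baseline), 10)
  expect_equal(unique(em$perturbation), 10)
  expect_equal(unique(em$steady), 10)

  # step 0 -> 20 at load onset
  rs <- manual_rate_series(1, 1, function(ni, ctx, ci, t) 20 * (t >= 0))
  em <- epoch_means(rs)
  expect_equal(unique(em$baseline), 0)
  expect_equal(unique(em$perturbation), 20)

  # linear ramp 0 -> 30 across the perturbation window: mean 15 with a small
  # sampling-edge allowance
  rs <- manual_rate_series(1, 1, function(ni, ctx, ci, t)
    ifelse(t >= 0, 30 * t / 300, 0))
  em <- epoch_means(rs)
  expect_equal(unique(em$perturbation), 15, tolerance = 0.5)

  expect_error(epoch_means(demo_rates(),
                           epoch_windows(baseline = c(-400, -300))),
               "empty")
})

test_that("trial-averaged traces equal the mean of trial traces", {
  rs <- demo_rates()
  arr <- rs$rates$contra[[3]]
  expect_equal(rs$avg$contra[[3]], rowMeans(arr, dims = 2))
  expect_true(all(arr >= 0))
})

test_that("trials too short for a wider aligned window are excluded loudly", {
  s <- tiny_session(trials_per_cell = 2)
  wide <- epoch_windows(baseline = c(-700, 0))   # needs 700 ms of hold
  expect_warning(rs <- smooth_spike_trains(s, windows = wide), "excluding")
  n_kept <- sum(vapply(rs$trial_ids, function(ctx) sum(lengths(ctx)),
                       numeric(1)))
  expect_equal(n_kept, 0)    # every trial holds only 600 ms before the load
})
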