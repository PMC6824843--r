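step_trace <- function(base = 10, jump = 10, at = 50, times = seq(-200, 299),
                       noise_sd = 1, seed = 1) {
  set.seed(seed)
  base + stats::rnorm(length(times), 0, noise_sd) + jump * (times >= at)
}

test_that("a clean step is detected at its onset", {
  times <- seq(-200, 299)
  tr <- step_trace(base = 10, jump = 10, at = 50, noise_sd = 1)
  det <- detect_onset(tr, times)
  expect_equal(det$onset_ms, 50)
  expect_equal(det$baseline_mean, 10, tolerance = 0.3)
  expect_false(det$degenerate)
})

test_that("a sub-dwell blip does not trigger and inhibition does", {
  times <- seq(-200, 299)
  blip <- step_trace(jump = 0, noise_sd = 1) +
    20 * (times >= 100 & times < 115)        # 15 ms excursion only
  expect_true(is.na(detect_onset(blip, times)$onset_ms))

  drop <- step_trace(base = 30, jump = -15, at = 80, noise_sd = 1)
  expect_equal(detect_onset(drop, times)$onset_ms, 80)
  expect_true(is.na(detect_onset(drop, times, two_sided = FALSE)$onset_ms))
})

test_that("onset detection is translation-equivariant and scale-invariant", {
  times <- seq(-200, 299)
  tr <- step_trace(at = 60)
  d0 <- detect_onset(tr, times)
  # shift the trace (and the clock) by 40 ms
  d1 <- detect_onset(tr, times + 40, baseline_window = c(-160, 40),
                     search_window = c(40, 340))
  expect_equal(d1$onset_ms, d0$onset_ms + 40)
  d2 <- detect_onset(3.7 * tr, times)
  expect_equal(d2$onset_ms, d0$onset_ms)
})

test_that("degenerate baselines and short traces are flagged", {
  times <- seq(-200, 299)
  flat <- rep(5, length(times))
  det <- detect_onset(flat, times)
  expect_true(det$degenerate)
  expect_true(is.na(det$onset_ms))
  expect_error(detect_onset(flat[1:210], times[1:210]), "dwell")
})

test_that("best-load averaging pools the peak load and its 45-degree neighbours", {
  # response only on the load at 90 degrees (index 2)
  rs <- manual_rate_series(1, 3, function(ni, ctx, ci, t)
    10 + 15 * (ci == 2) * (t >= 25))
  bla <- best_load_average(rs, "n01", "contra")
  expect_equal(bla$best_load_index, 2L)
  expect_equal(sort(bla$selected_loads), c(1L, 2L, 3L))
  expect_false(bla$tie)
  # pooled over three loads, only one responds: a third of the response
  expect_equal(mean(bla$trace[rs$times_ms >= 100]), 10 + 5, tolerance = 0.2)

  # equal response everywhere: tie resolved to the lowest index
  rs2 <- manual_rate_series(1, 2, function(ni, ctx, ci, t) 10 + 5 * (t >= 0))
  bla2 <- best_load_average(rs2, "n01", "contra")
  expect_true(bla2$tie)
  expect_equal(bla2$best_load_index, 0L)
})

test_that("population onset matches a shared latency and orders contexts", {
  # all neurons share a 25 ms latency, half inhibited: rectification must
  # prevent cancellation
  set.seed(12)
  rs <- manual_rate_series(6, 4, function(ni, ctx, ci, t) {
    sgn <- if (ni %% 2 == 0) -1 else 1
    lat <- if (ctx == "contra") 25 else 35
    pmax(20 + sgn * 12 * (t >= lat), 0)
  }, noise_sd = 2)
  pop_c <- population_onset(rs, "contra")
  pop_i <- population_onset(rs, "ipsi")
  expect_true(pop_c$onset_ms >= 25 && pop_c$onset_ms <= 35)
  expect_true(pop_i$onset_ms >= 35 && pop_i$onset_ms <= 45)
  expect_gt(pop_i$onset_ms, pop_c$onset_ms)
  expect_error(population_onset(rs, "contra", neuron_ids = "n01"), ">= 2")
})

test_that("onset contrast pairs neurons and reports medians and correlations", {
  set.seed(3)
  n <- 12
  oc <- data.frame(neuron_id = sprintf("n%02d", 1:n), context = "contra",
                   onset_ms = 30 + stats::rpois(n, 5),
                   best_load_index = 0L, baseline_mean = 10, baseline_sd = 1)
  oi <- oc
  oi$context <- "ipsi"
  oi$onset_ms <- oc$onset_ms + 10
  mags <- rbind(
    data.frame(neuron_id = oc$neuron_id, context = "contra",
               magnitude_hz_per_nm = stats::runif(n, 20, 40)),
    data.frame(neuron_id = oc$neuron_id, context = "ipsi",
               magnitude_hz_per_nm = stats::runif(n, 10, 20))
  )
  res <- onset_contrast(oc, oi, mags)
  expect_equal(res$median_difference, -10)
  expect_equal(res$fraction_contra_earlier, 1)
  expect_lt(res$p, 0.01)
  expect_lt(res$z, 0)

  oi_same <- oi
  oi_same$onset_ms <- oc$onset_ms
  expect_equal(onset_contrast(oc, oi_same, mags)$z, 0)

  expect_error(onset_contrast(oc[1:3, ], oi[1:3, ], mags), "5")
})
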