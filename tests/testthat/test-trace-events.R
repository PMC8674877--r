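# Iterative event detection on time-resolved traces.

test_that("isolated spikes over a flat background are found and the loop converges", {
  counts <- rep(1L, 100)
  counts[c(20, 70)] <- 50L
  ev <- detect_events(make_trace(counts), k = 3)
  expect_identical(ev$event_index, c(20L, 70L))
  expect_lte(ev$n_iterations, 3L)
  expect_true(ev$converged)
  expect_equal(ev$background_mean, 1)
  # intensities are background-subtracted
  expect_equal(ev$intensity, c(49, 49))
})

test_that("degenerate traces yield no events, not errors", {
  ev_const <- detect_events(make_trace(rep(5L, 200)))
  expect_length(ev_const, 0L)
  ev_zero <- detect_events(make_trace(rep(0L, 200)))
  expect_length(ev_zero, 0L)
  expect_equal(ev_zero$background_mean, 0)
  expect_equal(ev_zero$background_sd, 0)
})

test_that("invalid inputs are rejected", {
  expect_error(time_trace(numeric(0), integer(0)), "empty")
  expect_error(time_trace(c(1, 1, 2), c(0L, 1L, 2L)), "increasing")
  expect_error(time_trace(1:3, c(-1L, 0L, 1L)), "non-negative")
  expect_error(detect_events(make_trace(rep(1L, 10)), k = 0), "positive")
  expect_error(detect_events(make_trace(rep(1L, 10)), k = -2), "positive")
})

test_that("detection matches a naive reference loop on random spiked traces", {
  set.seed(42)
  for (rep_i in 1:30) {
    n <- sample(200:1000, 1)
    lambda <- sample(c(1, 2, 5), 1)
    counts <- rpois(n, lambda)
    n_spikes <- sample(0:12, 1)
    if (n_spikes > 0) {
      at <- sample(n, n_spikes)
      counts[at] <- counts[at] + rpois(n_spikes, 60)
    }
    mode <- if (rep_i %% 2) "gaussian" else "poisson"
    ev <- detect_events(make_trace(counts), k = 3, mode = mode,
                        merge_adjacent = FALSE)
    ref <- oracle_detect(counts, k = 3, mode = mode)
    expect_identical(ev$event_index, as.integer(ref$idx))
    expect_equal(ev$background_mean, ref$av)
    expect_equal(ev$background_sd, ref$sd)
  }
})

test_that("detection is idempotent at convergence", {
  set.seed(7)
  counts <- rpois(2000, 2)
  counts[sample(2000, 15)] <- 120L
  ev <- detect_events(make_trace(counts), mode = "poisson",
                      merge_adjacent = FALSE)
  residual <- counts[-ev$event_index]
  ev2 <- detect_events(make_trace(residual), mode = "poisson")
  expect_length(ev2, 0L)
})

test_that("adjacent above-threshold dwells merge into one summed event", {
  counts <- rep(2L, 300)
  counts[100:101] <- c(80L, 40L)  # one cell split across a dwell boundary
  counts[200] <- 60L
  merged <- detect_events(make_trace(counts))
  split <- detect_events(make_trace(counts), merge_adjacent = FALSE)
  expect_length(merged, 2L)
  expect_length(split, 3L)
  expect_equal(merged$event_index[1], 100L)  # index of the max dwell
  expect_equal(merged$n_dwells, c(2L, 1L))
  expect_equal(merged$raw_counts, c(120, 60))
  expect_equal(merged$intensity[1],
               120 - 2 * merged$background_mean)
})

test_that("hitting the iteration cap warns and flags non-convergence", {
  counts <- rep(1L, 100); counts[c(5, 50)] <- 50L
  expect_warning(ev <- detect_events(make_trace(counts), max_iter = 1L),
                 "iteration cap")
  expect_false(ev$converged)
})

test_that("poisson mode dispersion never drops below sqrt(Av)", {
  # narrow sample: sd < sqrt(mean), so poisson mode is more conservative
  counts <- c(rep(4L, 95), rep(5L, 5))
  counts[10] <- 9L  # above gaussian threshold, below poisson threshold
  g <- detect_events(make_trace(counts), mode = "gaussian")
  p <- detect_events(make_trace(counts), mode = "poisson")
  expect_gte(p$threshold, p$background_mean + 3 * sqrt(p$background_mean) - 1e-9)
  expect_true(10L %in% g$event_index)
  expect_false(10L %in% p$event_index)
})
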