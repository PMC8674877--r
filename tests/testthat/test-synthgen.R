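# Synthetic-data generator: determinism, counting statistics, ground-truth
# distributions.

test_that("fixed seeds give bit-identical traces and images", {
  p <- trace_sim_params(duration_s = 10, seed = 77)
  s1 <- simulate_trace(p); s2 <- simulate_trace(p)
  expect_identical(s1$trace$counts, s2$trace$counts)
  expect_identical(s1$truth, s2$truth)
  ip <- image_sim_params(n_cells = 8, seed = 78)
  i1 <- simulate_image(ip); i2 <- simulate_image(ip)
  expect_identical(i1$pixel_map$channels, i2$pixel_map$channels)
  expect_identical(i1$brightfield$pixels, i2$brightfield$pixels)
})

test_that("generators restore the caller's RNG state", {
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(simulate_trace(trace_sim_params(duration_s = 5,
                                                         seed = 99)))
  r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("zero event rate gives a pure Poisson background", {
  sim <- simulate_trace(trace_sim_params(duration_s = 20, event_rate = 0,
                                         background_mean = 2, seed = 5))
  expect_equal(nrow(sim$truth), 0L)
  y <- as.numeric(sim$trace$counts)
  expect_lt(abs(mean(y) - 2), 0.1)
  expect_lt(abs(var(y) - 2), 0.2)   # Poisson: variance = mean
})

test_that("introduced-event counts follow Poisson statistics with thinning", {
  r <- 10; T <- 60; eta <- 0.5
  sim <- simulate_trace(trace_sim_params(duration_s = T, event_rate = r,
                                         eta = eta, seed = 6))
  expect_lt(abs(nrow(sim$truth) - r * T * eta), 4 * sqrt(r * T * eta))
})

test_that("a crowded trace triggers the coincidence warning", {
  expect_warning(
    simulate_trace(trace_sim_params(duration_s = 0.3, event_rate = 1000,
                                    seed = 8)),
    "coincidence")
})

test_that("dead fraction controls the Rh channel", {
  clean <- simulate_image(image_sim_params(n_cells = 6, dead_fraction = 0,
                                           noise = FALSE, seed = 9))
  expect_true(all(clean$pixel_map$channels$`103Rh` == 0))
  stained <- simulate_image(image_sim_params(n_cells = 20, dead_fraction = 0.5,
                                             noise = FALSE, seed = 10))
  expect_gt(sum(stained$truth$dead), 0)
  expect_gt(max(stained$pixel_map$channels$`103Rh`), 0)
})

test_that("infeasible placements fail loudly", {
  expect_error(
    simulate_image(image_sim_params(image_size_px = c(40L, 40L),
                                    n_cells = 50L, seed = 11)),
    "non-overlapping")
})

test_that("droplet arrays are exact at zero noise and scale with amounts", {
  dr <- simulate_droplet_array(seq(0, 50, 10), slope_counts_per_fg = 120,
                               noise_cv = 0, seed = 1)
  expect_equal(dr$summed_intensities, 120 * dr$amounts_fg)
  cal <- fit_droplet_calibration(dr$amounts_fg, dr$summed_intensities)
  expect_equal(cal$slope, 120)
  expect_equal(cal$r_squared, 1)
  zero <- simulate_droplet_array(rep(0, 4), noise_cv = 0, seed = 1)
  expect_equal(zero$summed_intensities, rep(0, 4))
  expect_error(simulate_droplet_array(-1), ">= 0")
})

test_that("generated per-cell masses follow the specified lognormal", {
  sim <- simulate_trace(trace_sim_params(duration_s = 250, event_rate = 40,
                                         mass_median_fg = 2, mass_gsd = 1.5,
                                         seed = 12))
  m <- sim$truth$mass_fg
  expect_gt(length(m), 9000)
  ks <- suppressWarnings(ks.test(m, plnorm, meanlog = log(2),
                                 sdlog = log(1.5)))
  expect_lt(unname(ks$statistic), 0.02)
})
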