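# Dead-cell flagging and population statistics.

rh_table <- function(rh) data.frame(cell_id = seq_along(rh), sum_103Rh = rh)

test_that("bimodal Rh sums flag exactly the high (dead) mode", {
  set.seed(17)
  live <- rlnorm(50, log(10), 0.3)
  dead <- rlnorm(50, log(1000), 0.3)
  tab <- flag_dead_cells(rh_table(c(live, dead)), method = "otsu")
  expect_equal(tab$dead, rep(c(FALSE, TRUE), each = 50))
  # mad suits mostly-live samples: a few stained outliers over a live mode
  few_dead <- c(rlnorm(95, log(10), 0.3), rlnorm(5, log(1000), 0.3))
  tab_mad <- flag_dead_cells(rh_table(few_dead), method = "mad")
  expect_equal(which(tab_mad$dead), 96:100)
})

test_that("degenerate Rh channels never flag cells", {
  expect_warning(tab <- flag_dead_cells(rh_table(rep(0, 20)), method = "otsu"),
                 "all-zero")
  expect_false(any(tab$dead))
  # mad on a constant flags nothing
  tab2 <- flag_dead_cells(rh_table(rep(42, 20)), method = "mad")
  expect_false(any(tab2$dead))
  tab3 <- flag_dead_cells(rh_table(rep(42, 20)), method = "otsu")
  expect_false(any(tab3$dead))
})

test_that("a fixed threshold flags an entirely heat-killed sample", {
  set.seed(18)
  rh <- rlnorm(40, log(1000), 0.3)
  tab <- flag_dead_cells(rh_table(rh), method = "fixed", threshold = 100)
  expect_true(all(tab$dead))
  expect_error(flag_dead_cells(rh_table(rh), method = "fixed"), "threshold")
  expect_error(flag_dead_cells(rh_table(rh), rh_channel = "999X"), "Rh sums")
})

test_that("population summaries use the linear-interpolation quartile convention", {
  s <- population_summary(c(1, 2, 3, 4), "demo")
  expect_equal(s$median, 2.5)
  expect_equal(s$q25, 1.75)
  expect_equal(s$q75, 3.25)
  expect_equal(s$n, 4L)
  single <- population_summary(7)
  expect_true(all(unlist(single[c("mean", "median", "q25", "q75",
                                  "min", "max")]) == 7))
  set.seed(3)
  x <- rlnorm(101)
  expect_equal(unclass(population_summary(x))[-1],
               unclass(population_summary(sample(x)))[-1])
  expect_error(population_summary(numeric(0)), "empty")
})

test_that("the Welch test matches the textbook formulas", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  w <- welch_test(a, b)
  ref <- oracle_welch(a, b)
  expect_equal(w$t_statistic, ref$t)
  expect_equal(w$degrees_of_freedom, ref$df)
  expect_equal(w$p_value, ref$p)
  # identical samples: t = 0, p = 1
  w0 <- welch_test(a, a)
  expect_equal(w0$t_statistic, 0)
  expect_equal(w0$p_value, 1)
  # swapping groups negates t and preserves p
  w_ab <- welch_test(a, b * 2)
  w_ba <- welch_test(b * 2, a)
  expect_equal(w_ab$t_statistic, -w_ba$t_statistic)
  expect_equal(w_ab$p_value, w_ba$p_value)
  expect_error(welch_test(1, a), "n >= 2")
  expect_error(welch_test(c(1, 1), c(2, 2)), "zero variance")
})

test_that("size normalisation divides by diameter or sphere volume", {
  expect_equal(as.numeric(normalize_by_size(15, 15)), 1)
  expect_equal(as.numeric(normalize_by_size(15, 30)), 0.5)
  expect_equal(as.numeric(normalize_by_size(15, 15, mode = "volume")),
               15 / (pi * 15^3 / 6))
  expect_equal(attr(normalize_by_size(1, 1, mode = "volume"), "units"),
               "fg/um^3")
  expect_error(normalize_by_size(1, 0), "> 0")
})

test_that("ordered generators yield stochastically ordered summaries", {
  meds <- c(0.8, 1.8, 2.8, 8)   # monocyte-like through M2-like fixtures
  set.seed(25)
  observed <- vapply(seq_along(meds), function(i) {
    sim <- simulate_trace(trace_sim_params(duration_s = 20, event_rate = 10,
                                           mass_median_fg = meds[i],
                                           seed = 100 + i))
    population_summary(sim$truth$mass_fg)$median
  }, numeric(1))
  expect_true(all(diff(observed) > 0))
})
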