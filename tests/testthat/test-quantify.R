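# Mass quantification, transport efficiency, and detection limits
# (suspension arm).

cal100 <- fit_liquid_calibration(c(0, 1, 2), c(0, 100, 200))

test_that("the mass equation reproduces the hand unit-conversion example", {
  # 600 counts / (100 counts per ug/L) = 6 ug/L; 10 uL/min = 1.6667e-7 L/s;
  # x 3 ms dwell = 5e-10 L; 6 ug/L x 5e-10 L = 3e-9 ug = 3.0 fg
  expect_equal(event_mass(600, cal100, flow_uL_min = 10, dwell_s = 0.003), 3.0)
  expect_equal(event_mass(0, cal100), 0)
  # against the independent unit-by-unit oracle over random inputs
  set.seed(5)
  for (i in 1:10) {
    I <- runif(1, 0, 1e4); b <- runif(1, 10, 500)
    Fm <- runif(1, 1, 50); t <- runif(1, 1e-3, 1e-2); eta <- runif(1, 0.1, 1)
    cal <- list(slope = b, eta = 1)
    expect_equal(event_mass(I, cal, Fm, t, eta = eta),
                 oracle_mass_fg(I, b, Fm, t, eta))
  }
})

test_that("mass is linear in I, F, t, eta and inversely linear in b", {
  m0 <- event_mass(300, cal100, 10, 0.003)
  expect_equal(event_mass(600, cal100, 10, 0.003), 2 * m0)
  expect_equal(event_mass(300, cal100, 20, 0.003), 2 * m0)
  expect_equal(event_mass(300, cal100, 10, 0.006), 2 * m0)
  expect_equal(event_mass(300, cal100, 10, 0.003, eta = 0.5), m0 / 2)
  cal200 <- list(slope = 200, eta = 1)
  expect_equal(event_mass(300, cal200, 10, 0.003), m0 / 2)
})

test_that("mass quantification rejects invalid inputs", {
  expect_error(event_mass(-1, cal100), "negative intensity")
  expect_error(event_mass(1, list(slope = -5, eta = 1)), "slope")
  expect_error(event_mass(1, cal100, flow_uL_min = 0), "flow")
})

test_that("transport efficiency follows detected over expected counts", {
  # 1e5 particles/mL x 10 uL/min x 30 s = 500 expected
  expect_equal(as.numeric(transport_efficiency(100, 1e5, 10, 30)), 0.2)
  expect_equal(as.numeric(transport_efficiency(500, 1e5, 10, 30)), 1.0)
  expect_warning(eta0 <- transport_efficiency(0, 1e5, 10, 30), "zero")
  expect_equal(as.numeric(eta0), 0)
  expect_warning(transport_efficiency(600, 1e5, 10, 30), "exceeds 1")
  expect_error(transport_efficiency(10, 0, 10, 30), "positive")
})

test_that("the per-event LOD is three background sigmas through the calibration", {
  expect_equal(sc_lod(rep(5L, 150), cal100), 0)       # zero-variance background
  set.seed(9)
  bg <- rpois(500, 4)
  # independent two-line recomputation
  ref <- oracle_mass_fg(3 * sd(bg), 100, 10, 0.003)
  expect_equal(sc_lod(bg, cal100), ref)
  cal2 <- fit_liquid_calibration(c(0, 1, 2), c(0, 200, 400))
  expect_equal(sc_lod(bg, cal2), ref / 2)             # doubling slope halves LOD
  expect_error(sc_lod(rpois(50, 4), cal100), "insufficient")
})

test_that("calibrating an event set attaches masses consistent with event_mass", {
  counts <- rep(2L, 300); counts[c(40, 200)] <- c(102L, 202L)
  ev <- detect_events(make_trace(counts))
  ev <- calibrate_events(ev, cal100)
  expect_equal(ev$mass_fg, event_mass(ev$intensity, cal100, 10, 0.003))
  expect_true(all(ev$mass_fg >= 0))
  df <- as.data.frame(ev)
  expect_true("mass_fg" %in% names(df))
})
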