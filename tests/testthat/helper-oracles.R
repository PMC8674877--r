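# Independent reference implementations used as oracles. These deliberately
# mirror the definitions, not the package code paths.

# naive iterative threshold detector: returns the set of marked indices and
# the converged background mean/sd, written as a plain loop over a vector
oracle_detect <- function(y, k = 3, mode = "gaussian", max_iter = 100) {
  marked <- rep(FALSE, length(y))
  for (it in seq_len(max_iter)) {
    bg <- y[!marked]
    av <- mean(bg)
    sdv <- if (length(bg) > 1) sd(bg) else 0
    disp <- if (mode == "poisson") max(sdv, sqrt(av)) else sdv
    thr <- av + k * disp
    new_marks <- which(!marked & y > thr)
    if (length(new_marks) == 0) break
    marked[new_marks] <- TRUE
    if (all(marked)) break
  }
  list(idx = which(marked), av = mean(y[!marked]),
       sd = if (sum(!marked) > 1) sd(y[!marked]) else 0, threshold = thr)
}

# closed-form simple-regression slope/intercept
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# Welch statistic, Welch-Satterthwaite df and two-sided p from first
# principles
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# mass equation by explicit unit conversion: I/b ug/L, F uL/min -> L/s,
# times dwell s -> litres; ug -> fg
oracle_mass_fg <- function(I, slope, flow_uL_min, dwell_s, eta = 1) {
  conc_ug_per_L <- I / slope
  flow_L_per_s <- flow_uL_min * 1e-6 / 60
  eta * conc_ug_per_L * flow_L_per_s * dwell_s * 1e9
}

# convenience: wrap a counts vector as a single-channel trace
make_trace <- function(counts, dwell_s = 0.003, flow = 10) {
  time_trace(seq_along(counts) * dwell_s, counts, dwell_s = dwell_s,
             flow_uL_min = flow, channels = "195Pt")
}
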