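# icpcell

Quantitative single-cell elemental analysis by ICP-TOFMS, for analytical
chemists and mass-cytometry groups measuring absolute metal content (for
example platinum from cisplatin exposure, in femtograms per cell) in
individual cells by either of two orthogonal routes:

* **Suspension SC-ICP-MS** — cells nebulised one at a time produce count
  spikes over a Poisson instrument background in a time-resolved trace
  (3 ms dwell). `icpcell` detects events by iterative outlier
  thresholding, `T = Av + k * disp` with `disp = Stdv` or, for Poisson
  backgrounds, `max(Stdv, sqrt(Av))`, recomputed after removing marked
  events until convergence, and converts intensities to mass via liquid
  standards: `m_c = eta * F * t * I / b` (transport efficiency, flow,
  dwell, background-subtracted intensity over calibration slope).
* **LA-ICP-TOFMS imaging** — laser-rastered cytospins give one intensity
  map per isotope (2.5 x 2.5 um pixels from a 5 um spot at dosage 2 with
  2.5 um line overlap). `icpcell` segments cells in the co-registered
  bright-field image, transfers segments onto the maps, integrates
  per-channel sums, and calibrates them against gelatin microdroplet
  standards of known element amount; per-cell detection limits follow the
  Longerich 3-sigma formulation scaled by the mean cell footprint.

Around the two quantification cores: QC flagging (Rh-intercalator
dead-cell marker, morphology filters with auditable fail reasons),
population statistics (25-75 percentile summaries, Welch two-sample
tests, cell-size normalisation), a synthetic-data generator with ground
truth for end-to-end validation, pipeline drivers configured by YAML, and
a small CLI (`inst/cli/icpcell.R`).

## Worked example

Simulate a 50 s suspension acquisition (10 cells/s, lognormal platinum
masses with median 2 fg), detect and calibrate events, and summarise:

```r
library(icpcell)

sim <- simulate_trace(trace_sim_params(duration_s = 50, event_rate = 10,
                                       mass_median_fg = 2, seed = 42))
cal <- fit_liquid_calibration(c(0, 1, 2, 5), c(0, 100, 200, 500))
ev  <- detect_events(sim$trace, "195Pt", k = 5, mode = "poisson",
                     merge_adjacent = FALSE)
ev  <- calibrate_events(ev, cal)
print(ev)
print(population_summary(ev$mass_fg, "THP-1-like fixture"))
cat(sprintf("per-event LOD: %.3f fg\n", sc_lod(ev, cal)))
```

```
event_set: 498 event(s) on channel 195Pt
  threshold 9.113 counts (k = 5, mode = poisson), 4 iteration(s)
  background: mean 1.993, sd 1.424 counts
THP-1-like fixture: n = 498, median 2 fg (25-75%: 1.55-2.59), mean 2.17
per-event LOD: 0.021 fg
```

The detector converged in 4 iterations on a threshold of ~9 counts over a
~2-count Poisson background and found 498 events (505 cells were
generated; the difference is sub-threshold events and same-dwell
coincidences). The recovered median of 2 fg matches the generating
median; the 25-75 percentile band is what studies in this field report
per population. The per-event LOD of 0.021 fg is the smallest mass
distinguishable from this background through this calibration.

The imaging arm runs the same way from a bright-field image plus channel
maps — `segment_cells()`, `register_brightfield()`,
`transfer_and_integrate()`, `quantify_cells()` — or end to end through
`run_image_pipeline()` / `run_trace_pipeline()` with a YAML config. See
the methods vignette (`vignettes/icpcell-methods.Rmd`) for the models,
conventions and defaults.

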