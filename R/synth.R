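# Synthetic-data generator: traces, images and droplet arrays with known
# ground truth, so every pipeline stage can be validated end to end without
# instrument data. Statistical, not mechanistic: no plasma/aerosol transport
# physics is modelled.

# evaluate code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Parameters for synthetic single-cell ICP-MS traces
#'
#' Defaults mirror a typical suspension acquisition: 3 ms dwell, 10 uL/min
#' flow, a low-count Poisson instrument background, and lognormal per-cell
#' masses around 2 fg.
#'
#' @param duration_s acquisition length, s.
#' @param dwell_s dwell time, s.
#' @param background_mean Poisson background mean, counts per dwell.
#' @param event_rate introduced cell rate, events/s.
#' @param mass_median_fg,mass_gsd lognormal per-cell mass: median (fg) and
#'   geometric SD (> 1).
#' @param cal_slope liquid-calibration slope, counts per ug/L.
#' @param flow_uL_min sample flow, uL/min.
#' @param eta transport efficiency applied as thinning of introduced cells.
#' @param seed RNG seed (required for reproducible fixtures).
#' @return list of class `trace_sim_params`.
#' @export
trace_sim_params <- function(duration_s = 60, dwell_s = 0.003,
                             background_mean = 2, event_rate = 5,
                             mass_median_fg = 2, mass_gsd = 1.5,
                             cal_slope = 100, flow_uL_min = 10, eta = 1,
                             seed = 1L) {
  p <- as.list(environment())
  stopifnot(duration_s > 0, dwell_s > 0, background_mean >= 0,
            event_rate >= 0, mass_median_fg > 0, mass_gsd >= 1,
            cal_slope > 0, flow_uL_min > 0, eta > 0, eta <= 1)
  structure(p, class = "trace_sim_params")
}

#' Simulate a time-resolved single-cell ICP-MS trace
#'
#' Draws Poisson background counts for every dwell, introduces cells as a
#' Poisson process thinned by the transport efficiency, assigns each
#' surviving cell a lognormal mass, converts mass to expected counts by
#' inverting the mass equation under the given calibration slope, and adds
#' Poisson-distributed event counts to the hit dwells. Warns when more than
#' 20\% of event-carrying dwells hold two or more cells (coincidence regime,
#' where suspension analysis cannot exclude doublets).
#'
#' @param params a [trace_sim_params()].
#' @return list with `trace` (a [time_trace], channel `"195Pt"`) and `truth`
#'   (data.frame `dwell_index`, `time_s`, `mass_fg`; one row per introduced
#'   surviving cell).
#' @export
simulate_trace <- function(params) {
  stopifnot(inherits(params, "trace_sim_params"))
  p <- params
  with_seed(p$seed, {
    n <- as.integer(round(p$duration_s / p$dwell_s))
    counts <- stats::rpois(n, p$background_mean)
    n_intro <- stats::rpois(1, p$event_rate * p$duration_s)
    survive <- stats::runif(n_intro) <= p$eta
    n_ev <- sum(survive)
    truth <- data.frame(dwell_index = integer(0), time_s = numeric(0),
                        mass_fg = numeric(0))
    if (n_ev > 0) {
      idx <- sample.int(n, n_ev, replace = TRUE)
      mass <- stats::rlnorm(n_ev, meanlog = log(p$mass_median_fg),
                            sdlog = log(p$mass_gsd))
      vol_L <- p$flow_uL_min * 1e-6 / 60 * p$dwell_s
      expect_counts <- mass * p$cal_slope / (vol_L * 1e9)
      add <- stats::rpois(n_ev, expect_counts)
      for (i in seq_len(n_ev)) counts[idx[i]] <- counts[idx[i]] + add[i]
      multi <- sum(table(idx) >= 2L)
      if (length(unique(idx)) > 0 && multi / length(unique(idx)) > 0.2)
        warning("coincidence regime: > 20% of event dwells hold multiple ",
                "cells", call. = FALSE)
      ord <- order(idx)
      truth <- data.frame(dwell_index = idx[ord],
                          time_s = idx[ord] * p$dwell_s,
                          mass_fg = mass[ord])
    }
    list(trace = time_trace(seq_len(n) * p$dwell_s, counts,
                            dwell_s = p$dwell_s,
                            flow_uL_min = p$flow_uL_min,
                            channels = "195Pt"),
         truth = truth)
  })
}

#' Parameters for synthetic LA-ICP-TOFMS images
#'
#' Cells are rendered as discs (cytospun cells are near-circular) of normal
#' diameter around 15 um on a 2.5 um pixel grid: dark in the bright-field,
#' with uniform endogenous 31P/23Na per-pixel signal, a total 195Pt signal
#' proportional to the cell's true mass, and 103Rh painted only on
#' dead-flagged cells. Poisson pixel noise is added unless `noise = FALSE`.
#'
#' @param image_size_px `c(rows, cols)`.
#' @param pitch_um pixel pitch, um.
#' @param n_cells number of cells to place (non-overlapping).
#' @param diameter_mean_um,diameter_sd_um normal diameter distribution, um.
#' @param mass_median_fg,mass_gsd lognormal per-cell Pt mass (fg; gsd > 1).
#' @param slope_counts_per_fg imaging sensitivity: total counts painted per
#'   fg of cell mass.
#' @param background_mean Poisson per-pixel background mean (applied to all
#'   element channels), counts.
#' @param p_per_px,na_per_px endogenous 31P/23Na signal per cell pixel,
#'   counts.
#' @param dead_fraction fraction of cells flagged dead and painted with Rh.
#' @param rh_total_counts total Rh counts painted over a dead cell.
#' @param bf_background,bf_cell bright-field gray levels of background and
#'   cell interior.
#' @param boundary_perturb relative radial perturbation of the disc contour
#'   (0 = perfect discs; used for segmentation stress tests).
#' @param min_gap_px minimum pixel gap kept between cells.
#' @param noise add Poisson pixel noise? `FALSE` paints exact intensities.
#' @param seed RNG seed.
#' @return list of class `image_sim_params`.
#' @export
image_sim_params <- function(image_size_px = c(300L, 300L), pitch_um = 2.5,
                             n_cells = 40L, diameter_mean_um = 15,
                             diameter_sd_um = 1.5, mass_median_fg = 2,
                             mass_gsd = 1.6, slope_counts_per_fg = 400,
                             background_mean = 0.5, p_per_px = 60,
                             na_per_px = 40, dead_fraction = 0,
                             rh_total_counts = 5000, bf_background = 200,
                             bf_cell = 60, boundary_perturb = 0,
                             min_gap_px = 3L, noise = TRUE, seed = 1L) {
  p <- as.list(environment())
  stopifnot(all(image_size_px >= 10), pitch_um > 0, n_cells >= 0,
            diameter_mean_um > 0, diameter_sd_um >= 0, mass_median_fg > 0,
            mass_gsd >= 1, slope_counts_per_fg > 0, background_mean >= 0,
            dead_fraction >= 0, dead_fraction <= 1, boundary_perturb >= 0,
            boundary_perturb < 1)
  structure(p, class = "image_sim_params")
}

#' Simulate a bright-field image and co-registered elemental pixel map
#'
#' @param params an [image_sim_params()].
#' @return list with `brightfield` (a [brightfield]), `pixel_map` (a
#'   [pixel_map] with channels `31P`, `23Na`, `195Pt`, `103Rh`) and `truth`
#'   (data.frame `cell_id`, centre `row`/`col`, `radius_px`, `area_px`,
#'   `diameter_um`, `mass_fg`, `dead`).
#' @export
simulate_image <- function(params) {
  stopifnot(inherits(params, "image_sim_params"))
  p <- params
  with_seed(p$seed, {
    nr <- p$image_size_px[1]; nc <- p$image_size_px[2]
    diam_um <- pmax(stats::rnorm(p$n_cells, p$diameter_mean_um,
                                 p$diameter_sd_um), 2 * p$pitch_um)
    radius_px <- diam_um / 2 / p$pitch_um
    # sequential non-overlap placement with bounded retries
    cx <- cy <- numeric(p$n_cells)
    for (i in seq_len(p$n_cells)) {
      placed <- FALSE
      margin <- radius_px[i] * (1 + p$boundary_perturb) + 2
      for (try in seq_len(500L)) {
        y <- stats::runif(1, margin, nr - margin)
        x <- stats::runif(1, margin, nc - margin)
        if (i == 1L || all(sqrt((cx[seq_len(i - 1L)] - x)^2 +
                                (cy[seq_len(i - 1L)] - y)^2) >=
                           radius_px[seq_len(i - 1L)] + radius_px[i] +
                           p$min_gap_px)) {
          cx[i] <- x; cy[i] <- y; placed <- TRUE; break
        }
      }
      if (!placed)
        stop("could not place ", p$n_cells, " non-overlapping cells in a ",
             nr, " x ", nc, " frame", call. = FALSE)
    }

    mass <- stats::rlnorm(p$n_cells, log(p$mass_median_fg), log(p$mass_gsd))
    dead <- stats::runif(p$n_cells) < p$dead_fraction

    bf <- matrix(p$bf_background, nr, nc)
    zero <- matrix(0, nr, nc)
    chan <- list(`31P` = zero, `23Na` = zero, `195Pt` = zero, `103Rh` = zero)
    area_px <- integer(p$n_cells)
    rowg <- matrix(seq_len(nr), nr, nc)
    colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (i in seq_len(p$n_cells)) {
      rr <- rowg - cy[i]; cc <- colg - cx[i]
      if (p$boundary_perturb > 0) {
        ang <- atan2(rr, cc)
        ph <- stats::runif(3, 0, 2 * pi); amp <- stats::runif(3, 0, p$boundary_perturb / 3)
        pert <- 1 + amp[1] * sin(2 * ang + ph[1]) +
          amp[2] * sin(3 * ang + ph[2]) + amp[3] * sin(5 * ang + ph[3])
        inside <- sqrt(rr^2 + cc^2) <= radius_px[i] * pert
      } else {
        inside <- rr^2 + cc^2 <= radius_px[i]^2
      }
      area_px[i] <- sum(inside)
      bf[inside] <- p$bf_cell
      chan$`31P`[inside] <- chan$`31P`[inside] + p$p_per_px
      chan$`23Na`[inside] <- chan$`23Na`[inside] + p$na_per_px
      chan$`195Pt`[inside] <- chan$`195Pt`[inside] +
        mass[i] * p$slope_counts_per_fg / area_px[i]
      if (dead[i])
        chan$`103Rh`[inside] <- chan$`103Rh`[inside] +
          p$rh_total_counts / area_px[i]
    }
    if (p$noise) {
      chan <- lapply(chan, function(m)
        matrix(stats::rpois(length(m), m + p$background_mean), nr, nc))
      bf <- bf + matrix(stats::rnorm(length(bf), 0, 2), nr, nc)
    }
    list(brightfield = brightfield(bf, p$pitch_um),
         pixel_map = pixel_map(chan, pitch_um = p$pitch_um),
         truth = data.frame(cell_id = seq_len(p$n_cells), row = cy, col = cx,
                            radius_px = radius_px, area_px = area_px,
                            diameter_um = diam_um, mass_fg = mass,
                            dead = dead))
  })
}

#' Simulate a gelatin-microdroplet calibration array
#'
#' Summed intensities `slope * amount * (1 + e)` with multiplicative
#' Gaussian noise of coefficient of variation `noise_cv`.
#'
#' @param amounts_fg element amount per droplet, fg, >= 0.
#' @param slope_counts_per_fg generating sensitivity.
#' @param pixels_per_droplet pixels over which a droplet is ablated
#'   (metadata for per-pixel sensitivity rescaling).
#' @param noise_cv relative noise SD, default 0.
#' @param seed RNG seed.
#' @return list with `amounts_fg`, `summed_intensities`,
#'   `pixels_per_droplet`, `true_slope`.
#' @export
simulate_droplet_array <- function(amounts_fg, slope_counts_per_fg = 100,
                                   pixels_per_droplet = 100L, noise_cv = 0,
                                   seed = 1L) {
  if (any(amounts_fg < 0)) stop("amounts must be >= 0", call. = FALSE)
  with_seed(seed, {
    noise <- if (noise_cv > 0)
      stats::rnorm(length(amounts_fg), 0, noise_cv) else 0
    sums <- pmax(slope_counts_per_fg * amounts_fg * (1 + noise), 0)
    list(amounts_fg = amounts_fg, summed_intensities = sums,
         pixels_per_droplet = pixels_per_droplet,
         true_slope = slope_counts_per_fg)
  })
}
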