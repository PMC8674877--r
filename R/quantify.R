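#' Convert event intensity to element mass per cell
#'
#' Implements the standard single-cell ICP-MS mass equation
#' \deqn{m_c = \eta \; F \; t \; I / b}
#' where `I/b` is the concentration equivalent (ug/L) of the
#' background-subtracted event intensity under the liquid calibration slope
#' `b`, `F t` is the sample volume nebulised during one dwell, and `eta` is
#' the transport efficiency of the liquid standards (assumed 1 for a
#' full-consumption introduction system at low flow).
#'
#' Units: `F` in uL/min is converted to L/s (`* 1e-6 / 60`), multiplied by
#' the dwell `t` in seconds to a volume in litres; ug/L times litres gives
#' ug, reported as femtograms (`* 1e9`).
#'
#' @param I background-subtracted event intensity, counts (vectorised).
#' @param cal a liquid `icp_calibration` from [fit_liquid_calibration()] (or
#'   any object with positive `$slope` in counts per ug/L and `$eta`).
#' @param flow_uL_min sample flow F in uL/min, default 10.
#' @param dwell_s dwell (integration) time t in seconds, default 0.003.
#' @param eta transport efficiency override; defaults to `cal$eta` (1 if
#'   absent).
#' @return mass per event in femtograms.
#' @examples
#' cal <- fit_liquid_calibration(c(0, 1, 2), c(0, 100, 200))
#' event_mass(600, cal)  # 3 fg at 10 uL/min, 3 ms
#' @export
event_mass <- function(I, cal, flow_uL_min = 10, dwell_s = 0.003, eta = NULL) {
  if (is.null(eta)) eta <- if (!is.null(cal$eta)) cal$eta else 1
  if (any(I < 0)) stop("negative intensity; subtract background upstream",
                       call. = FALSE)
  if (!is.numeric(cal$slope) || cal$slope <= 0)
    stop("calibration slope must be > 0", call. = FALSE)
  if (flow_uL_min <= 0 || dwell_s <= 0)
    stop("flow and dwell must be > 0", call. = FALSE)
  if (eta <= 0 || eta > 1) stop("eta must be in (0, 1]", call. = FALSE)
  conc_ug_L <- I / cal$slope
  vol_L <- flow_uL_min * 1e-6 / 60 * dwell_s
  eta * conc_ug_L * vol_L * 1e9
}

#' Calibrate an event set to femtogram masses
#'
#' Applies [event_mass()] to every detected event of an
#' [event_set][detect_events()], using the flow and dwell recorded on the
#' set.
#'
#' @param events an [event_set][detect_events()].
#' @param cal liquid calibration.
#' @param eta transport efficiency override (see [event_mass()]).
#' @return The event set with a `mass_fg` element added.
#' @export
calibrate_events <- function(events, cal, eta = NULL) {
  stopifnot(inherits(events, "event_set"))
  events$mass_fg <- event_mass(events$intensity, cal,
                               flow_uL_min = events$flow_uL_min,
                               dwell_s = events$dwell_s, eta = eta)
  events
}

#' Transport efficiency from a particle standard
#'
#' Fraction of introduced particles (metal-labelled polystyrene beads of
#' known number concentration) that produce a detected event; reports the
#' actual cell-number bias of suspension introduction. Typical values are
#' around 20\% for cells/beads, while liquid standards at low flow approach
#' 100\%.
#'
#' @param n_detected detected event count.
#' @param particle_per_mL particle number concentration, particles per mL.
#' @param flow_uL_min sample flow, uL/min.
#' @param duration_s acquisition duration, seconds.
#' @return Estimated transport efficiency fraction, with attribute `warning`
#'   set when the estimate exceeds 1 (more events than introduced particles)
#'   or when `n_detected` is 0.
#' @examples
#' # 100 events from 500 introduced particles
#' transport_efficiency(100, particle_per_mL = 1e5,
#'                      flow_uL_min = 10, duration_s = 30)
#' @export
transport_efficiency <- function(n_detected, particle_per_mL, flow_uL_min,
                                 duration_s) {
  if (particle_per_mL <= 0 || flow_uL_min <= 0 || duration_s <= 0)
    stop("expected particle number must be positive", call. = FALSE)
  if (n_detected < 0) stop("n_detected must be >= 0", call. = FALSE)
  expected <- particle_per_mL * (flow_uL_min / 1000 / 60) * duration_s
  eta <- n_detected / expected
  warn <- NULL
  if (eta > 1) {
    warn <- "estimated transport efficiency exceeds 1"
    warning(warn, call. = FALSE)
  } else if (n_detected == 0) {
    warn <- "no events detected; efficiency estimate is zero"
    warning(warn, call. = FALSE)
  }
  structure(eta, warning = warn)
}

#' Per-event limit of detection for suspension analysis
#'
#' Smallest element mass per cell event distinguishable from the Poisson
#' instrument background: three background standard deviations converted to
#' mass through the liquid calibration, i.e.
#' `event_mass(3 * sd(background), cal, F, t)`.
#'
#' @param background either a [time_trace] (a segment containing no events —
#'   run [detect_events()] first and pass the residual background), a numeric
#'   vector of background dwell counts, or an [event_set][detect_events()]
#'   whose converged `background_sd` is used directly.
#' @param cal liquid calibration.
#' @param flow_uL_min,dwell_s,eta see [event_mass()]. When `background` is a
#'   `time_trace` or `event_set` its recorded flow/dwell are the defaults.
#' @param channel channel to use when `background` is a multi-channel trace.
#' @param min_points minimum number of background dwells required,
#'   default 100.
#' @return LOD in femtograms per cell event.
#' @export
sc_lod <- function(background, cal, flow_uL_min = NULL, dwell_s = NULL,
                   eta = NULL, channel = 1L, min_points = 100L) {
  if (inherits(background, "event_set")) {
    sdv <- background$background_sd
    npts <- NA_integer_
    if (is.null(flow_uL_min)) flow_uL_min <- background$flow_uL_min
    if (is.null(dwell_s)) dwell_s <- background$dwell_s
  } else {
    y <- if (inherits(background, "time_trace")) {
      if (is.null(flow_uL_min)) flow_uL_min <- background$flow_uL_min
      if (is.null(dwell_s)) dwell_s <- background$dwell_s
      as.numeric(background$counts[, channel])
    } else as.numeric(background)
    npts <- length(y)
    if (npts < min_points)
      stop("insufficient background: ", npts, " < ", min_points, " points",
           call. = FALSE)
    sdv <- stats::sd(y)
  }
  if (is.null(flow_uL_min)) flow_uL_min <- 10
  if (is.null(dwell_s)) dwell_s <- 0.003
  event_mass(3 * sdv, cal, flow_uL_min = flow_uL_min, dwell_s = dwell_s,
             eta = eta)
}
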