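#' Detect single-cell events by iterative outlier thresholding
#'
#' Separates transient cell events from the instrument background of a
#' time-resolved single-cell ICP-MS trace. The background of such traces is
#' Poisson-distributed detector noise; a cell passing the plasma adds a short
#' (sub-dwell) burst of counts to one dwell. The detector iterates: compute
#' the mean `Av` and standard deviation `Stdv` of all currently unmarked
#' dwells, set the threshold `Av + k * disp`, mark dwells strictly above it as
#' events and remove them, then recompute, until an iteration marks no new
#' dwell (or `max_iter` is reached, which is flagged).
#'
#' The dispersion term `disp` is `Stdv` for `mode = "gaussian"`. Because at
#' low count rates the noise is Poisson rather than normal, `mode = "poisson"`
#' uses `max(Stdv, sqrt(Av))`, which never under-states the spread of a
#' Poisson background whose sample happens to be narrow. Both modes share the
#' same loop.
#'
#' Ties with the threshold count as background (strict `>`), so a
#' zero-variance trace yields no events. Adjacent above-threshold dwells are
#' merged into one event with summed background-subtracted intensity by
#' default (`merge_adjacent = TRUE`), since a ~300-400 us cell transient
#' spans at most one 3 ms dwell and a spillover split across a dwell boundary
#' must not be double-counted.
#'
#' @param trace a [time_trace].
#' @param channel isotope channel label or column index. Default first
#'   channel.
#' @param k threshold multiplier (dimensionless), default 3.
#' @param mode `"gaussian"` (dispersion = Stdv) or `"poisson"`
#'   (dispersion = max(Stdv, sqrt(Av))).
#' @param merge_adjacent merge runs of adjacent above-threshold dwells into
#'   single events (summed intensity)? Default `TRUE`. With `FALSE` each
#'   above-threshold dwell is its own event.
#' @param max_iter iteration cap, default 100.
#' @return An object of class `event_set`: list with
#'   \describe{
#'     \item{event_index}{dwell index of each event (index of the maximum
#'       dwell for merged events), sorted, unique}
#'     \item{event_time_s}{event times}
#'     \item{intensity}{background-subtracted counts per event (dwell count
#'       minus background mean; summed over merged dwells)}
#'     \item{raw_counts}{raw summed counts per event}
#'     \item{n_dwells}{dwells merged into each event}
#'     \item{background_mean, background_sd}{mean/SD of the converged
#'       non-event dwells (the `Av`/`Stdv` of the final state)}
#'     \item{threshold}{final converged threshold, counts}
#'     \item{n_iterations}{iterations run}
#'     \item{history}{data.frame of Av, Stdv, threshold, n_marked per
#'       iteration}
#'     \item{converged}{`FALSE` if the iteration cap was hit (also warns)}
#'   }
#' @examples
#' set.seed(1)
#' cnt <- rpois(500, 2); cnt[c(50, 300)] <- 80
#' tr <- time_trace(seq_len(500) * 0.003, cnt, channels = "195Pt")
#' ev <- detect_events(tr, "195Pt")
#' ev
#' @seealso [event_mass()] to calibrate intensities to femtograms,
#'   [sc_lod()] for the detection limit.
#' @export
detect_events <- function(trace, channel = 1L, k = 3, mode = c("gaussian", "poisson"),
                          merge_adjacent = TRUE, max_iter = 100L) {
  stopifnot(inherits(trace, "time_trace"))
  mode <- match.arg(mode)
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("k must be a positive scalar", call. = FALSE)
  y <- as.numeric(trace$counts[, channel])
  n <- length(y)
  if (n == 0L) stop("empty trace", call. = FALSE)

  is_event <- logical(n)
  hist_av <- hist_sd <- hist_thr <- numeric(0)
  hist_nm <- integer(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    bg <- y[!is_event]
    av <- mean(bg)
    sdv <- if (length(bg) > 1L) stats::sd(bg) else 0
    disp <- if (mode == "poisson") max(sdv, sqrt(av)) else sdv
    thr <- av + k * disp
    new_ev <- !is_event & y > thr
    hist_av <- c(hist_av, av); hist_sd <- c(hist_sd, sdv)
    hist_thr <- c(hist_thr, thr); hist_nm <- c(hist_nm, sum(new_ev))
    if (!any(new_ev)) { converged <- TRUE; break }
    is_event <- is_event | new_ev
    if (all(is_event)) { converged <- TRUE; break }  # degenerate: nothing left
  }
  if (!converged)
    warning("event detection hit the iteration cap (", max_iter,
            ") without converging", call. = FALSE)

  bg <- y[!is_event]
  bg_mean <- if (length(bg)) mean(bg) else 0
  bg_sd <- if (length(bg) > 1L) stats::sd(bg) else 0
  final_thr <- hist_thr[length(hist_thr)]

  idx <- which(is_event)
  if (length(idx) == 0L) {
    ev_index <- integer(0); inten <- raw <- numeric(0); ndw <- integer(0)
  } else if (merge_adjacent) {
    run_id <- cumsum(c(1L, diff(idx) > 1L))
    ev_index <- as.integer(tapply(idx, run_id, function(i) i[which.max(y[i])]))
    raw <- as.numeric(tapply(y[idx], run_id, sum))
    ndw <- as.integer(tapply(idx, run_id, length))
    inten <- raw - ndw * bg_mean
  } else {
    ev_index <- idx; raw <- y[idx]; ndw <- rep(1L, length(idx))
    inten <- raw - bg_mean
  }
  ord <- order(ev_index)
  structure(list(
    event_index = ev_index[ord],
    event_time_s = trace$time_s[ev_index[ord]],
    intensity = pmax(inten[ord], 0),
    raw_counts = raw[ord],
    n_dwells = ndw[ord],
    background_mean = bg_mean,
    background_sd = bg_sd,
    threshold = final_thr,
    n_iterations = it,
    k = k, mode = mode,
    channel = if (is.numeric(channel)) colnames(trace$counts)[channel] else channel,
    dwell_s = trace$dwell_s, flow_uL_min = trace$flow_uL_min,
    history = data.frame(iteration = seq_along(hist_av), Av = hist_av,
                         Stdv = hist_sd, threshold = hist_thr,
                         n_marked = hist_nm),
    converged = converged),
    class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("event_set: %d event(s) on channel %s\n",
              length(x$event_index), x$channel))
  cat(sprintf("  threshold %.3f counts (k = %g, mode = %s), %d iteration(s)%s\n",
              x$threshold, x$k, x$mode, x$n_iterations,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  background: mean %.3f, sd %.3f counts\n",
              x$background_mean, x$background_sd))
  invisible(x)
}

#' @export
summary.event_set <- function(object, ...) {
  print(object)
  if (length(object$intensity)) {
    cat("  event intensity (background-subtracted counts):\n")
    print(summary(object$intensity))
  }
  invisible(object)
}

#' @export
length.event_set <- function(x) length(x$event_index)

#' Plot a detected event set over its threshold history
#'
#' @param x an [event_set][detect_events()].
#' @param trace optionally, the originating [time_trace] to show the full
#'   trace with events highlighted; otherwise event intensities are shown.
#' @param ... passed to [graphics::plot()].
#' @export
plot.event_set <- function(x, trace = NULL, ...) {
  if (!is.null(trace)) {
    y <- as.numeric(trace$counts[, x$channel])
    graphics::plot(trace$time_s, y, type = "h", col = "grey60",
                   xlab = "time (s)", ylab = "counts per dwell", ...)
    graphics::points(x$event_time_s, y[x$event_index], col = "red3", pch = 16,
                     cex = 0.6)
    graphics::abline(h = x$threshold, col = "blue3", lty = 2)
  } else {
    graphics::plot(x$event_time_s, x$intensity, type = "h",
                   xlab = "time (s)", ylab = "event intensity (counts)", ...)
  }
  invisible(x)
}

#' Export an event set as a data.frame
#'
#' One row per detected event with index, time, intensity and, when a
#' calibration has been applied via [event_mass()], the mass in femtograms.
#'
#' @param x an [event_set][detect_events()].
#' @param ... unused.
#' @export
as.data.frame.event_set <- function(x, ...) {
  df <- data.frame(event_index = x$event_index, time_s = x$event_time_s,
                   intensity_counts = x$intensity, n_dwells = x$n_dwells)
  if (!is.null(x$mass_fg)) df$mass_fg <- x$mass_fg
  df
}

#' Write an event table and detection report
#'
#' Writes the per-event table as delimited text and the detection report
#' (per-iteration Av, Stdv, threshold, and the converged state) as JSON.
#'
#' @param events an [event_set][detect_events()].
#' @param table_path path for the delimited event table.
#' @param report_path optional path for the JSON detection report.
#' @return `table_path`, invisibly.
#' @export
write_events <- function(events, table_path, report_path = NULL) {
  stopifnot(inherits(events, "event_set"))
  utils::write.table(as.data.frame(events), table_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report_path)) {
    rep <- list(channel = events$channel, k = events$k, mode = events$mode,
                n_events = length(events$event_index),
                n_iterations = events$n_iterations,
                converged = events$converged,
                background_mean = events$background_mean,
                background_sd = events$background_sd,
                threshold = events$threshold,
                history = events$history)
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE)
  }
  invisible(table_path)
}
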