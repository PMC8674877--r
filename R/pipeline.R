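# Pipeline drivers binding the stages into reproducible, self-describing
# runs: a structured (YAML) config in, tables + JSON reports out, every
# effective parameter echoed into the report.

stop_config <- function(...) {
  stop(structure(class = c("icpcell_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Read and validate a run configuration
#'
#' Configurations are single YAML files (or equivalent R lists) with a
#' `mode` of `"trace"` or `"image"`; see [run_trace_pipeline()] and
#' [run_image_pipeline()] for the recognised fields. Channel roles must be
#' distinct; unknown roles are rejected before any computation.
#'
#' @param config path to a YAML file, or a list.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_config("config must be a list or YAML file")
  if (is.null(config$mode) || !config$mode %in% c("trace", "image"))
    stop_config("config$mode must be 'trace' or 'image'")
  if (!is.null(config$roles)) {
    known <- c("element", "anchor", "rh", "endogenous")
    bad <- setdiff(names(config$roles), known)
    if (length(bad))
      stop_config("unknown channel role(s): ", paste(bad, collapse = ", "))
    vals <- unlist(config$roles)
    if (anyDuplicated(vals))
      stop_config("channel roles must name distinct channels")
  }
  structure(config, class = c("run_config", "list"))
}

read_liquid_cal_file <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("concentration_ug_L", "intensity")
  if (!all(need %in% names(df)))
    stop_config("liquid calibration file needs columns ",
                paste(need, collapse = ", "))
  df
}

read_droplet_cal_file <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("amount_fg", "summed_intensity")
  if (!all(need %in% names(df)))
    stop_config("droplet calibration file needs columns ",
                paste(need, collapse = ", "))
  df
}

run_report <- function(config, extra) {
  c(list(package = "icpcell",
         version = as.character(utils::packageVersion("icpcell")),
         r_version = as.character(getRversion()),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         config = unclass(config)),
    extra)
}

#' Run the suspension (trace) pipeline
#'
#' Detect events, fit the liquid calibration, quantify event masses,
#' compute the per-event detection limit and summarise the population.
#' Writes `events.tsv`, `detection_report.json` and `summary.json` into the
#' output directory.
#'
#' Config fields: `mode: trace`; `trace` (path, see [read_trace()]);
#' `channel` (default first); `detection` (`k`, `mode`, `merge_adjacent`);
#' `calibration` (`file` with columns `concentration_ug_L`, `intensity`, or
#' inline `concentrations`/`intensities`); `eta` (default 1); `outdir`;
#' `seed` (recorded; the pipeline itself is deterministic).
#'
#' @param config path to YAML config, or list (see [read_run_config()]).
#' @return report list (invisibly written as `summary.json`), containing the
#'   calibrated [event_set][detect_events()] under `$events`.
#' @export
run_trace_pipeline <- function(config) {
  config <- read_run_config(config)
  if (config$mode != "trace") stop_config("config mode is not 'trace'")
  if (is.null(config$calibration))
    stop_config("missing calibration for quantification")
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  trace <- if (is.character(config$trace)) read_trace(config$trace)
           else config$trace
  det <- config$detection %||% list()
  ev <- detect_events(trace,
                      channel = config$channel %||% 1L,
                      k = det$k %||% 3,
                      mode = det$mode %||% "gaussian",
                      merge_adjacent = det$merge_adjacent %||% TRUE,
                      max_iter = det$max_iter %||% 100L)
  cal_cfg <- config$calibration
  cal_df <- if (!is.null(cal_cfg$file)) read_liquid_cal_file(cal_cfg$file)
            else data.frame(concentration_ug_L = cal_cfg$concentrations,
                            intensity = cal_cfg$intensities)
  cal <- fit_liquid_calibration(cal_df$concentration_ug_L, cal_df$intensity,
                                eta = config$eta %||% 1)
  ev <- calibrate_events(ev, cal)
  lod <- sc_lod(ev, cal)
  summ <- population_summary(ev$mass_fg, label = config$label %||% "trace")

  write_events(ev, file.path(outdir, "events.tsv"),
               file.path(outdir, "detection_report.json"))
  report <- run_report(config, list(
    n_events = length(ev), n_iterations = ev$n_iterations,
    converged = ev$converged, threshold_counts = ev$threshold,
    background_mean = ev$background_mean, background_sd = ev$background_sd,
    calibration = list(slope = cal$slope, intercept = cal$intercept,
                       r_squared = cal$r_squared, eta = cal$eta),
    lod_fg = lod, summary = as.data.frame(summ)))
  jsonlite::write_json(report[names(report) != "events"],
                       file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", force = TRUE)
  report$events <- ev
  invisible(report)
}

#' Run the imaging (LA-ICP-TOFMS) pipeline
#'
#' Segment the bright-field image, register it onto the pixel map, transfer
#' and integrate the segments, fit the microdroplet calibration, quantify
#' the element channel, flag dead cells on the Rh channel, and summarise
#' live passing cells. Writes `mask.tif` (16-bit labelled mask),
#' `cells.tsv` and `summary.json`.
#'
#' Config fields: `mode: image`; `brightfield` (`file`, `scale_um`);
#' `channels` (`files`: channel -> matrix path, `pitch_um`); `roles`
#' (`element`, `anchor`, `rh`); `segmentation`
#' (`min_diameter_um`, `max_diameter_um`, `min_circularity`,
#' `min_convexity`, `watershed`); `register` (logical, default `TRUE`;
#' `FALSE` uses the identity/scale transform for pre-aligned frames);
#' `calibration` (`file` with `amount_fg`, `summed_intensity`, or inline
#' vectors; optional `droplet_pixels`); `dead_method` (mad/otsu/fixed,
#' default `mad` — robust for unstained samples; otsu suits a clear
#' live/dead split; optional `dead_threshold`); `include_flagged` (default
#' `FALSE`: dead and
#' morphology-failing cells are excluded from the summary); `outdir`.
#'
#' @param config path to YAML config, or list.
#' @return report list with the quantified `cell_segments` under `$cells`.
#' @export
run_image_pipeline <- function(config) {
  config <- read_run_config(config)
  if (config$mode != "image") stop_config("config mode is not 'image'")
  if (is.null(config$calibration))
    stop_config("missing calibration for quantification")
  roles <- config$roles %||% list(element = "195Pt", anchor = "31P",
                                  rh = "103Rh")
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  bf <- if (!is.null(config$brightfield$file))
    read_brightfield(config$brightfield$file, config$brightfield$scale_um)
  else config$brightfield
  pmap <- if (!is.null(config$channels$files))
    read_pixel_map(unlist(config$channels$files),
                   pitch_um = config$channels$pitch_um %||% c(2.5, 2.5))
  else config$channels

  seg_cfg <- config$segmentation %||% list()
  seg <- segment_cells(bf,
                       min_diameter_um = seg_cfg$min_diameter_um %||% 8,
                       max_diameter_um = seg_cfg$max_diameter_um %||% 30,
                       min_circularity = seg_cfg$min_circularity %||% 0.4,
                       min_convexity = seg_cfg$min_convexity %||% 0.85,
                       watershed = seg_cfg$watershed %||% TRUE)

  transform <- if (isFALSE(config$register)) NULL
               else if (nrow(seg$table))
                 register_brightfield(bf, pmap,
                                      anchor_channel = roles$anchor %||% "31P")
               else NULL

  elem <- roles$element %||% "195Pt"
  bg_px <- if (nrow(seg$table))
    mean(background_pixels(pmap, seg, elem)) else 0
  bgv <- stats::setNames(rep(0, length(pmap$channels)), names(pmap$channels))
  bgv[elem] <- bg_px
  seg <- transfer_and_integrate(seg, pmap, transform,
                                background_per_pixel = bgv)

  cal_cfg <- config$calibration
  cal_df <- if (!is.null(cal_cfg$file)) read_droplet_cal_file(cal_cfg$file)
            else data.frame(amount_fg = cal_cfg$amounts_fg,
                            summed_intensity = cal_cfg$summed_intensities)
  cal <- fit_droplet_calibration(cal_df$amount_fg, cal_df$summed_intensity)
  seg <- quantify_cells(seg, cal, elem)

  rh <- roles$rh %||% "103Rh"
  if (paste0("sum_", rh) %in% names(seg$table) && nrow(seg$table)) {
    # default mad: robust when few or no cells are stained; configure otsu
    # for samples with a clear live/dead split
    seg <- flag_dead_cells(seg, rh_channel = rh,
                           method = config$dead_method %||% "mad",
                           threshold = config$dead_threshold)
  } else seg$table$dead <- logical(nrow(seg$table))

  tab <- seg$table
  keep <- if (isTRUE(config$include_flagged)) rep(TRUE, nrow(tab))
          else tab$pass & !tab$dead & !tab$edge_touching
  mass_col <- paste0("mass_", elem, "_fg")
  lod <- if (nrow(tab[keep, ]) > 0)
    la_lod(background_pixels(pmap, seg, elem), cal,
           mean_pixels_per_cell = mean(tab$map_area_px[keep]),
           droplet_pixels = cal_cfg$droplet_pixels %||% 1)
  else NA_real_
  summ <- if (any(keep))
    as.data.frame(population_summary(tab[[mass_col]][keep],
                                     label = config$label %||% "image"))
  else data.frame(label = config$label %||% "image", n = 0L)

  write_mask_tiff(seg$labels, file.path(outdir, "mask.tif"))
  utils::write.table(tab, file.path(outdir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- run_report(config, list(
    n_segments = nrow(tab), n_passing = sum(tab$pass),
    n_dead = sum(tab$dead), n_analysed = sum(keep),
    registration = if (!is.null(transform))
      list(shift_px = transform$shift_px, score = transform$score)
    else "identity",
    calibration = list(slope = cal$slope, intercept = cal$intercept,
                       r_squared = cal$r_squared),
    background_per_pixel = bg_px, lod_fg = lod, summary = summ))
  jsonlite::write_json(report, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", force = TRUE)
  report$cells <- seg
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
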