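#' Transfer segments onto a pixel map and integrate channel intensities
#'
#' Maps each bright-field segment footprint into the elemental pixel-map
#' frame through a registration transform and sums the pixel intensities of
#' every channel over the (unique) covered map pixels. Segments reaching
#' outside the map are clipped and flagged `edge_touching` rather than
#' dropped.
#'
#' @param segments a [cell_segments][segment_cells()].
#' @param pmap a [pixel_map].
#' @param transform a [bf_transform][register_brightfield()]; defaults to the
#'   identity with the scale implied by the two pixel sizes.
#' @param background_per_pixel per-pixel instrument background (counts) to
#'   subtract from each covered map pixel before summation, one value or a
#'   named vector per channel; default 0. Use the mean intensity of cell-free
#'   regions (see [background_pixels()]).
#' @return The `cell_segments` object with columns `map_area_px`,
#'   `edge_touching` and one `sum_<channel>` column per channel added to its
#'   table.
#' @export
transfer_and_integrate <- function(segments, pmap, transform = NULL,
                                   background_per_pixel = 0) {
  stopifnot(inherits(segments, "cell_segments"), inherits(pmap, "pixel_map"))
  if (is.null(transform))
    transform <- identity_transform(
      c(segments$scale_um / pmap$pitch_um[2],
        segments$scale_um / pmap$pitch_um[1]))
  stopifnot(inherits(transform, "bf_transform"))
  d <- dim(pmap)
  chans <- names(pmap$channels)
  bg <- rep(background_per_pixel, length.out = length(chans))
  if (!is.null(names(background_per_pixel)))
    bg <- ifelse(chans %in% names(background_per_pixel),
                 background_per_pixel[chans], 0)
  names(bg) <- chans

  tab <- segments$table
  n <- nrow(tab)
  sums <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
  map_area <- integer(n)
  edge <- logical(n)
  lab <- segments$labels
  idx_by_lab <- split(seq_along(lab), lab)
  idx_by_lab[["0"]] <- NULL

  for (i in seq_len(n)) {
    ii <- idx_by_lab[[as.character(tab$cell_id[i])]]
    if (is.null(ii)) next
    r <- (ii - 1L) %% nrow(lab) + 1L
    c <- (ii - 1L) %/% nrow(lab) + 1L
    # bright-field pixel centre -> containing map pixel, then shift
    mr <- floor((r - 0.5) * transform$scale[1]) + 1L + transform$shift_px[1]
    mc <- floor((c - 0.5) * transform$scale[2]) + 1L + transform$shift_px[2]
    keep <- mr >= 1L & mr <= d[1] & mc >= 1L & mc <= d[2]
    edge[i] <- any(!keep)
    lin <- unique((mc[keep] - 1L) * d[1] + mr[keep])
    map_area[i] <- length(lin)
    for (ch in chans)
      sums[i, ch] <- sum(pmap$channels[[ch]][lin]) - bg[ch] * length(lin)
  }
  tab$map_area_px <- map_area
  tab$edge_touching <- edge
  for (ch in chans) tab[[paste0("sum_", ch)]] <- pmax(sums[, ch], 0)
  segments$table <- tab
  segments$map_pitch_um <- pmap$pitch_um
  segments
}

#' Mean per-pixel background of a pixel map outside all segments
#'
#' @param pmap a [pixel_map].
#' @param segments optional [cell_segments][segment_cells()] already
#'   transferred to the map frame; if omitted the whole image is used.
#' @param channel channel label.
#' @return mean counts per cell-free pixel.
#' @export
background_pixels <- function(pmap, segments = NULL, channel) {
  m <- pmap$channels[[channel]]
  if (is.null(segments)) return(as.numeric(m))
  # crude cell-free mask: map-frame footprint of all segments dilated by 1 px
  d <- dim(m)
  occ <- matrix(FALSE, d[1], d[2])
  tr <- identity_transform(c(segments$scale_um / pmap$pitch_um[2],
                             segments$scale_um / pmap$pitch_um[1]))
  lab <- segments$labels
  ii <- which(lab > 0L)
  r <- (ii - 1L) %% nrow(lab) + 1L
  c <- (ii - 1L) %/% nrow(lab) + 1L
  mr <- floor((r - 0.5) * tr$scale[1]) + 1L
  mc <- floor((c - 0.5) * tr$scale[2]) + 1L
  for (dr in -1:1) for (dc in -1:1) {
    rr <- mr + dr; cc <- mc + dc
    k <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2]
    occ[cbind(rr[k], cc[k])] <- TRUE
  }
  as.numeric(m[!occ])
}

#' Element mass per cell from a summed image intensity
#'
#' Converts a per-cell summed intensity to femtograms through the
#' gelatin-microdroplet calibration slope. The calibration is fitted with a
#' free intercept, but quantification uses the slope only: the instrument
#' background is a per-pixel quantity and is subtracted per pixel before
#' summation (see `background_per_pixel` in [transfer_and_integrate()]), not
#' as a single per-cell intercept. Masses are floored at zero.
#'
#' @param sum_intensity background-subtracted summed intensity, counts
#'   (vectorised).
#' @param cal a droplet `icp_calibration` (slope in counts per fg).
#' @return mass in femtograms, >= 0.
#' @examples
#' cal <- fit_droplet_calibration(c(0, 10, 20), c(0, 1000, 2000))
#' cell_mass_from_image(500, cal)  # 5 fg
#' @export
cell_mass_from_image <- function(sum_intensity, cal) {
  if (!is.numeric(cal$slope) || cal$slope <= 0)
    stop("calibration slope must be > 0", call. = FALSE)
  pmax(sum_intensity / cal$slope, 0)
}

#' Quantify element masses for integrated segments
#'
#' Adds a `mass_<channel>_fg` column for each requested channel using
#' [cell_mass_from_image()].
#'
#' @param segments a [cell_segments][segment_cells()] after
#'   [transfer_and_integrate()].
#' @param cal droplet calibration.
#' @param channels channel label(s) to quantify, e.g. `"195Pt"`.
#' @return the `cell_segments` with mass columns added.
#' @export
quantify_cells <- function(segments, cal, channels) {
  stopifnot(inherits(segments, "cell_segments"))
  for (ch in channels) {
    col <- paste0("sum_", ch)
    if (!col %in% names(segments$table))
      stop("no integrated sums for channel ", ch,
           "; run transfer_and_integrate() first", call. = FALSE)
    segments$table[[paste0("mass_", ch, "_fg")]] <-
      cell_mass_from_image(segments$table[[col]], cal)
  }
  segments
}

#' Per-cell limit of detection for LA-ICP-TOFMS imaging
#'
#' Longerich-style detection limit: three standard deviations of the
#' cell-free background pixel intensities, converted to mass through the
#' per-pixel sensitivity, times the average number of pixels covered by a
#' cell. Because summed intensities are additive in the contained amount, a
#' calibration slope fitted on droplet sums (counts per fg) is already the
#' per-pixel sensitivity: a pixel holding m fg reads `slope * m` counts.
#' Only when the calibration's y-axis is the mean per-pixel droplet
#' intensity must the slope be rescaled by the droplet's pixel footprint
#' (`droplet_pixels`).
#'
#' @param background_pixels numeric vector of cell-free background pixel
#'   intensities, counts.
#' @param cal droplet `icp_calibration` (slope counts per fg).
#' @param mean_pixels_per_cell average pixels per segmented cell, >= 1.
#' @param droplet_pixels rescaling for mean-per-pixel (not summed) droplet
#'   calibrations: per-pixel sensitivity = `slope / droplet_pixels`.
#'   Default 1 (summed-intensity calibration).
#' @return per-cell LOD in femtograms.
#' @examples
#' cal <- fit_droplet_calibration(c(0, 10), c(0, 1000))  # 100 counts/fg
#' la_lod(rep(c(0, 4), 50), cal, mean_pixels_per_cell = 30)
#' @export
la_lod <- function(background_pixels, cal, mean_pixels_per_cell,
                   droplet_pixels = 1) {
  if (length(background_pixels) == 0L)
    stop("empty background sample", call. = FALSE)
  if (mean_pixels_per_cell < 1)
    stop("mean_pixels_per_cell must be >= 1", call. = FALSE)
  if (!is.numeric(cal$slope) || cal$slope <= 0)
    stop("calibration slope must be > 0", call. = FALSE)
  per_pixel_sens <- cal$slope / droplet_pixels
  3 * stats::sd(background_pixels) / per_pixel_sens * mean_pixels_per_cell
}
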