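#' Multi-channel elemental pixel map
#'
#' Container for LA-ICP-TOFMS signal intensity maps: one 2D grid of counts
#' per isotope channel on a common physical pixel pitch. Coordinates are
#' 0-based row-major pixel centres; `grid[i, j]` is row i (y), column j (x).
#'
#' @param channels named list of numeric matrices (counts per pixel), all the
#'   same dimension, non-negative.
#' @param pitch_um pixel pitch `c(dx, dy)` in micrometres (a scalar is
#'   recycled). Default `c(2.5, 2.5)`, the pitch of a 5 um square spot at
#'   dosage 2 with 2.5 um line overlap.
#' @param origin_um physical offset of pixel (0, 0) centre, default
#'   `c(0, 0)`.
#' @return Object of class `pixel_map`.
#' @seealso [compute_pixel_pitch()], [read_pixel_map()]
#' @export
pixel_map <- function(channels, pitch_um = c(2.5, 2.5), origin_um = c(0, 0)) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("channels must be a named list of matrices", call. = FALSE)
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L)
    stop("all channel grids must share the same shape", call. = FALSE)
  if (any(vapply(channels, function(m) any(m < 0), logical(1))))
    stop("intensities must be >= 0", call. = FALSE)
  if (length(pitch_um) == 1L) pitch_um <- rep(pitch_um, 2L)
  if (any(pitch_um <= 0)) stop("pixel pitch must be > 0", call. = FALSE)
  structure(list(channels = lapply(channels, as.matrix),
                 pitch_um = as.numeric(pitch_um),
                 origin_um = as.numeric(origin_um)),
            class = "pixel_map")
}

#' @export
print.pixel_map <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("pixel_map: %d x %d px at %.3g x %.3g um [%s]\n",
              d[1], d[2], x$pitch_um[1], x$pitch_um[2],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.pixel_map <- function(x) dim(x$channels[[1]])

#' Bright-field microscopy image
#'
#' Grayscale bright-field image of the region of interest acquired before
#' ablation; cells appear dark on a light background. Used for segmentation
#' and for registration onto the elemental pixel maps.
#'
#' @param pixels numeric matrix of grayscale intensities.
#' @param scale_um physical size of one pixel in micrometres (isotropic).
#' @return Object of class `brightfield`.
#' @export
brightfield <- function(pixels, scale_um) {
  pixels <- as.matrix(pixels)
  if (scale_um <= 0) stop("pixel scale must be > 0", call. = FALSE)
  structure(list(pixels = pixels, scale_um = scale_um), class = "brightfield")
}

#' @export
print.brightfield <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("brightfield: %d x %d px at %.3g um/px\n", d[1], d[2],
              x$scale_um))
  invisible(x)
}

#' @export
dim.brightfield <- function(x) dim(x$pixels)

#' Pixel pitch from laser-ablation raster geometry
#'
#' For a square laser spot rastered in fixed-dosage mode, the along-track
#' pitch is the spot size divided by the dosage (number of overlapping shots
#' per spot length) and the across-track pitch is the spot size minus the
#' overlap of adjacent lines. A 5 um spot at dosage 2 with 2.5 um line
#' overlap gives the common 2.5 x 2.5 um pixel.
#'
#' @param spot_size_um square spot edge length, um.
#' @param dosage integer >= 1, shots per spot length along the scan.
#' @param line_overlap_um overlap of adjacent lines in y, um; must be
#'   smaller than the spot.
#' @return `c(dx, dy)` in micrometres.
#' @examples
#' compute_pixel_pitch(5, 2, 2.5)  # 2.5 x 2.5 um
#' @export
compute_pixel_pitch <- function(spot_size_um, dosage, line_overlap_um = 0) {
  if (spot_size_um <= 0) stop("spot size must be > 0", call. = FALSE)
  if (dosage < 1 || dosage != round(dosage))
    stop("dosage must be a positive integer", call. = FALSE)
  if (line_overlap_um < 0 || line_overlap_um >= spot_size_um)
    stop("line overlap must be in [0, spot size)", call. = FALSE)
  c(dx = spot_size_um / dosage, dy = spot_size_um - line_overlap_um)
}

#' Equivalent diameter of a pixel footprint
#'
#' Diameter of the circle with the same area as `area_pixels` pixels of pitch
#' `dx` x `dy`: `2 * sqrt(area * dx * dy / pi)`. This is how segmented cell
#' sizes in pixel units are reported in micrometres.
#'
#' @param area_pixels pixel count, >= 1 (vectorised).
#' @param pitch_um pixel pitch `c(dx, dy)` um, scalar recycled. Default 2.5.
#' @return equivalent diameter(s), um.
#' @examples
#' equivalent_diameter(29, 2.5)  # ~15.2 um: a discrete disc of radius 3 px
#' @export
equivalent_diameter <- function(area_pixels, pitch_um = c(2.5, 2.5)) {
  if (any(area_pixels < 1)) stop("area must be >= 1 pixel", call. = FALSE)
  if (length(pitch_um) == 1L) pitch_um <- rep(pitch_um, 2L)
  2 * sqrt(area_pixels * pitch_um[1] * pitch_um[2] / pi)
}

# ---- input / output ------------------------------------------------------

#' Read / write pixel maps
#'
#' Two interchange formats are supported. Delimited text: one matrix file per
#' channel named `<prefix><channel>.tsv` (no header/rownames). Multi-page
#' TIFF: one page per channel, channel names supplied separately (TIFF page
#' descriptions are not portable).
#'
#' @param paths named character vector: channel label -> matrix file path
#'   (for `read_pixel_map`).
#' @param pitch_um,origin_um see [pixel_map()].
#' @return A [pixel_map].
#' @export
read_pixel_map <- function(paths, pitch_um = c(2.5, 2.5), origin_um = c(0, 0)) {
  if (is.null(names(paths))) stop("paths must be named by channel", call. = FALSE)
  ch <- lapply(paths, function(p)
    as.matrix(utils::read.table(p, header = FALSE, sep = "\t")))
  ch <- lapply(ch, unname)
  pixel_map(ch, pitch_um = pitch_um, origin_um = origin_um)
}

#' @rdname read_pixel_map
#' @param pmap a [pixel_map].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix, default `"chan_"`.
#' @return `write_pixel_map`: named vector of written paths, invisibly.
#' @export
write_pixel_map <- function(pmap, dir, prefix = "chan_") {
  stopifnot(inherits(pmap, "pixel_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(pmap$channels), function(nm) {
    p <- file.path(dir, paste0(prefix, nm, ".tsv"))
    utils::write.table(pmap$channels[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read a bright-field image
#'
#' Reads a grayscale TIFF/PNG (via the tiff/png readers) or a delimited
#' matrix, by file extension. Multi-channel images are averaged to
#' grayscale.
#'
#' @param path image path (`.tif`, `.tiff`, `.png`, else delimited text).
#' @param scale_um physical pixel size, um.
#' @return A [brightfield].
#' @export
read_brightfield <- function(path, scale_um) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  }
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)
  brightfield(unname(px), scale_um)
}

#' @rdname read_brightfield
#' @param bf a [brightfield].
#' @return `write_brightfield`: `path`, invisibly.
#' @export
write_brightfield <- function(bf, path) {
  stopifnot(inherits(bf, "brightfield"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- bf$pixels / max(bf$pixels, 1)
    tiff::writeTIFF(px, path, bits.per.sample = 16L)
  } else {
    utils::write.table(bf$pixels, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a labelled segmentation mask as 16-bit TIFF
#'
#' Background pixels are 0, the pixels of cell n carry the value n, the
#' standard interchange for per-cell masks.
#'
#' @param labels integer label matrix (0 = background).
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @return `read_mask_tiff`: integer label matrix.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
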