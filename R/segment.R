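#' Segment cells in a bright-field image
#'
#' Extracts candidate cell segments from a bright-field image (cells dark on
#' a light background): Otsu threshold on the inverted image, hole filling,
#' connected components, and an optional distance-transform watershed to
#' split touching cells. Each segment is scored by equivalent diameter,
#' circularity (`4 * pi * area / perimeter^2`) and convexity (pixel area over
#' convex-hull area) and filtered; segments failing a filter are kept with a
#' fail reason so that debris, doublets and clusters excluded from analysis
#' remain auditable.
#'
#' Default filters (all configurable): diameter 8-30 um — monocytes and
#' macrophages run around 15-20 um — minimum circularity 0.4, minimum
#' convexity 0.85.
#'
#' @param bf a [brightfield].
#' @param min_diameter_um,max_diameter_um accepted equivalent-diameter range,
#'   um.
#' @param min_circularity,min_convexity accepted shape-score minima in
#'   [0, 1].
#' @param watershed split touching cells by distance-transform watershed?
#'   Default `TRUE`.
#' @param watershed_tolerance minimum object-height separation for the
#'   watershed (in distance-map units, i.e. pixels), default 1.
#' @return Object of class `cell_segments`: list with
#'   \describe{
#'     \item{labels}{integer matrix, 0 = background, n = segment id}
#'     \item{table}{data.frame: `cell_id`, centroid `row`/`col` (bright-field
#'       px), `area_px`, `eq_diameter_um`, `circularity`, `convexity`,
#'       `pass`, `fail_reason`}
#'     \item{scale_um}{bright-field pixel size}
#'   }
#' @examples
#' \donttest{
#' sim <- simulate_image(image_sim_params(n_cells = 5, seed = 7))
#' seg <- segment_cells(sim$brightfield)
#' seg
#' }
#' @export
segment_cells <- function(bf, min_diameter_um = 8, max_diameter_um = 30,
                          min_circularity = 0.4, min_convexity = 0.85,
                          watershed = TRUE, watershed_tolerance = 1) {
  stopifnot(inherits(bf, "brightfield"))
  if (min_diameter_um >= max_diameter_um)
    stop("min_diameter_um must be < max_diameter_um", call. = FALSE)
  if (min_circularity < 0 || min_circularity > 1 ||
      min_convexity < 0 || min_convexity > 1)
    stop("shape-score minima must be in [0, 1]", call. = FALSE)

  px <- bf$pixels
  rng <- range(px)
  empty <- structure(list(labels = matrix(0L, nrow(px), ncol(px)),
                          table = empty_segment_table(),
                          scale_um = bf$scale_um),
                     class = "cell_segments")
  if (rng[2] <= rng[1]) return(empty)  # blank image: zero segments

  inv <- (rng[2] - px) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(inv))
  mask <- EBImage::fillHull(EBImage::Image(inv > thr))
  if (sum(mask) == 0) return(empty)

  lab <- if (watershed) {
    EBImage::watershed(EBImage::distmap(mask),
                       tolerance = watershed_tolerance)
  } else {
    EBImage::bwlabel(mask)
  }
  lab_m <- matrix(as.integer(EBImage::imageData(lab)), nrow(px), ncol(px))
  n_seg <- max(lab_m)
  if (n_seg == 0L) return(empty)

  shp <- EBImage::computeFeatures.shape(lab)
  area <- shp[, "s.area"]
  perim <- pmax(shp[, "s.perimeter"], 1)
  circ <- pmin(4 * pi * area / perim^2, 1)
  eqd <- equivalent_diameter(area, bf$scale_um)

  conv <- numeric(n_seg)
  cen_row <- cen_col <- numeric(n_seg)
  idx_by_lab <- split(seq_along(lab_m), lab_m)
  idx_by_lab[["0"]] <- NULL
  for (id in seq_len(n_seg)) {
    ii <- idx_by_lab[[as.character(id)]]
    r <- (ii - 1L) %% nrow(px) + 1L
    c <- (ii - 1L) %/% nrow(px) + 1L
    cen_row[id] <- mean(r); cen_col[id] <- mean(c)
    conv[id] <- convexity_px(r, c)
  }

  fail <- rep(NA_character_, n_seg)
  fail[eqd < min_diameter_um] <- "too_small"
  fail[eqd > max_diameter_um] <- "too_large"
  fail[is.na(fail) & circ < min_circularity] <- "low_circularity"
  fail[is.na(fail) & conv < min_convexity] <- "low_convexity"

  tab <- data.frame(cell_id = seq_len(n_seg), row = cen_row, col = cen_col,
                    area_px = as.integer(area), eq_diameter_um = eqd,
                    circularity = circ, convexity = conv,
                    pass = is.na(fail), fail_reason = fail,
                    row.names = NULL)
  structure(list(labels = lab_m, table = tab, scale_um = bf$scale_um),
            class = "cell_segments")
}

empty_segment_table <- function() {
  data.frame(cell_id = integer(0), row = numeric(0), col = numeric(0),
             area_px = integer(0), eq_diameter_um = numeric(0),
             circularity = numeric(0), convexity = numeric(0),
             pass = logical(0), fail_reason = character(0))
}

# convexity as solidity on the pixel grid: pixel area over the pixel count
# of the rasterised convex hull (pixels whose centres fall in the hull of
# the segment's pixel centres). A discrete disc scores 1; doublets and
# ragged debris score below 1.
convexity_px <- function(rows, cols) {
  if (length(rows) <= 3L) return(1)
  h <- grDevices::chull(cols, rows)
  hx <- cols[h]; hy <- rows[h]
  n <- length(h)
  grid <- expand.grid(r = min(rows):max(rows), c = min(cols):max(cols))
  # convex polygon membership: consistent cross-product sign over all edges
  inside <- rep(TRUE, nrow(grid))
  for (e in seq_len(n)) {
    x1 <- hx[e]; y1 <- hy[e]
    x2 <- hx[if (e == n) 1L else e + 1L]; y2 <- hy[if (e == n) 1L else e + 1L]
    cr <- (x2 - x1) * (grid$r - y1) - (y2 - y1) * (grid$c - x1)
    inside <- inside & cr <= 1e-9  # chull returns clockwise order
  }
  min(length(rows) / max(sum(inside), 1L), 1)
}

#' @export
print.cell_segments <- function(x, ...) {
  n <- nrow(x$table)
  cat(sprintf("cell_segments: %d segment(s), %d passing filters\n",
              n, sum(x$table$pass)))
  if (n > sum(x$table$pass)) {
    rs <- table(x$table$fail_reason)
    cat("  rejected:", paste(sprintf("%s (%d)", names(rs), rs),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.cell_segments <- function(object, ...) {
  print(object)
  ok <- object$table[object$table$pass, ]
  if (nrow(ok)) {
    cat("  equivalent diameter (um) of passing segments:\n")
    print(summary(ok$eq_diameter_um))
  }
  invisible(object)
}

#' @export
plot.cell_segments <- function(x, ...) {
  graphics::image(t(x$labels)[, nrow(x$labels):1],
                  col = c("white", grDevices::hcl.colors(max(max(x$labels), 1),
                                                         "viridis")),
                  axes = FALSE, asp = nrow(x$labels) / ncol(x$labels), ...)
  invisible(x)
}

#' @export
as.data.frame.cell_segments <- function(x, ...) x$table
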