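# Bright-field -> elemental-map registration. Cytospin slides are scanned in
# a fixed orientation, so the model is translation + known isotropic scale
# (the scale is the ratio of the bright-field pixel size to the map pitch);
# rotation is out of the default model.

#' Register a bright-field image onto an elemental pixel map
#'
#' Aligns the binarised bright-field cell mask with the binarised anchor
#' channel (an abundant endogenous element, 31P by default, which marks every
#' cell). The bright-field mask is resampled to the map pitch using the known
#' pixel sizes, and the translation maximising the overlap is found by FFT
#' cross-correlation; the returned score is the Dice coefficient of the two
#' masks after alignment.
#'
#' @param bf a [brightfield] (cells dark on light background).
#' @param pmap a [pixel_map].
#' @param anchor_channel channel used as alignment anchor, default `"31P"`.
#' @param score_floor Dice score below which a low-confidence warning is
#'   emitted, default 0.3.
#' @return Object of class `bf_transform`: list with `scale` (bright-field
#'   um/px divided by map pitch, length 2), `shift_px` (`c(dy, dx)` in map
#'   pixels), `score` (Dice in [0, 1]).
#' @export
register_brightfield <- function(bf, pmap, anchor_channel = "31P",
                                 score_floor = 0.3) {
  stopifnot(inherits(bf, "brightfield"), inherits(pmap, "pixel_map"))
  if (!anchor_channel %in% names(pmap$channels))
    stop("anchor channel ", anchor_channel, " not in pixel map", call. = FALSE)
  anchor <- pmap$channels[[anchor_channel]]
  if (max(anchor) <= min(anchor))
    stop("anchor channel is blank; cannot register", call. = FALSE)
  if (max(bf$pixels) <= min(bf$pixels))
    stop("bright-field image is blank; cannot register", call. = FALSE)

  a_mask <- binarize_high(anchor)
  b_mask_bf <- binarize_low(bf$pixels)  # cells are dark in bright-field
  scale <- c(bf$scale_um / pmap$pitch_um[2], bf$scale_um / pmap$pitch_um[1])
  b_mask <- resample_mask(b_mask_bf, scale)

  d <- dim(anchor)
  shift <- xcorr_peak(a_mask, b_mask, d)
  score <- dice_after_shift(a_mask, b_mask, shift, d)
  if (score < score_floor)
    warning(sprintf("low registration confidence (Dice = %.3f)", score),
            call. = FALSE)
  structure(list(scale = scale, shift_px = shift, score = score,
                 anchor_channel = anchor_channel),
            class = "bf_transform")
}

#' @export
print.bf_transform <- function(x, ...) {
  cat(sprintf(
    "bf_transform: scale (%.4g, %.4g), shift (dy = %d, dx = %d) map px, Dice %.3f\n",
    x$scale[1], x$scale[2], x$shift_px[1], x$shift_px[2], x$score))
  invisible(x)
}

#' Identity bright-field transform
#'
#' Convenience for synthetic data where the bright-field and map share a
#' grid.
#' @param scale row/col scale factors, default `c(1, 1)`.
#' @export
identity_transform <- function(scale = c(1, 1)) {
  structure(list(scale = scale, shift_px = c(0L, 0L), score = 1,
                 anchor_channel = NA_character_), class = "bf_transform")
}

binarize_high <- function(m) {
  rng <- range(m)
  norm <- (m - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm))
  norm > thr
}

binarize_low <- function(m) {
  rng <- range(m)
  norm <- (m - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(1 - norm))
  (1 - norm) > thr
}

# nearest-neighbour resample of a logical mask by row/col scale factors
resample_mask <- function(mask, scale) {
  out_d <- pmax(1L, as.integer(round(dim(mask) * scale)))
  rows <- pmin(dim(mask)[1], pmax(1L, as.integer(ceiling(
    (seq_len(out_d[1]) - 0.5) / scale[1]))))
  cols <- pmin(dim(mask)[2], pmax(1L, as.integer(ceiling(
    (seq_len(out_d[2]) - 0.5) / scale[2]))))
  mask[rows, cols, drop = FALSE]
}

# integer translation (dy, dx) maximising circular cross-correlation of two
# binary masks, both embedded in a d1 x d2 frame
xcorr_peak <- function(a, b, d) {
  A <- matrix(0, d[1], d[2]); B <- matrix(0, d[1], d[2])
  ra <- seq_len(min(d[1], nrow(a))); ca <- seq_len(min(d[2], ncol(a)))
  rb <- seq_len(min(d[1], nrow(b))); cb <- seq_len(min(d[2], ncol(b)))
  A[ra, ca] <- a[ra, ca]; B[rb, cb] <- b[rb, cb]
  cc <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(B)), inverse = TRUE))
  peak <- arrayInd(which.max(cc), d)
  sh <- peak - 1L
  sh <- ifelse(sh > d / 2, sh - d, sh)
  as.integer(sh)
}

dice_after_shift <- function(a, b, shift, d) {
  bs <- matrix(FALSE, d[1], d[2])
  rb <- seq_len(min(d[1], nrow(b))); cb <- seq_len(min(d[2], ncol(b)))
  src <- matrix(FALSE, d[1], d[2]); src[rb, cb] <- b[rb, cb]
  rows <- seq_len(d[1]) - shift[1]; cols <- seq_len(d[2]) - shift[2]
  ok_r <- rows >= 1 & rows <= d[1]; ok_c <- cols >= 1 & cols <= d[2]
  bs[which(ok_r), which(ok_c)] <- src[rows[ok_r], cols[ok_c]]
  inter <- sum(a & bs)
  2 * inter / (sum(a) + sum(bs))
}
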