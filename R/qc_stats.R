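# QC flagging and population statistics: rhodium-intercalator dead-cell
# flagging, quartile summaries (25-75 percentile as reported in this field),
# Welch two-sample tests, and cell-size normalisation.

#' Flag dead cells from the rhodium intercalator channel
#'
#' The Rh nucleic-acid intercalator enters only membrane-compromised cells,
#' so dead cells carry a high per-cell Rh sum. A per-sample threshold on the
#' Rh sums separates the live (low) and dead (high) modes:
#' \describe{
#'   \item{otsu}{1-D Otsu threshold between the two modes, computed on the
#'     log scale since per-cell Rh sums span decades (default). Note Otsu
#'     always splits the sample; on an unstained (unimodal) population use
#'     `mad` or `fixed`.}
#'   \item{mad}{`median + 5 * mad`; robust when almost no cells are dead. A
#'     constant Rh column never flags anything.}
#'   \item{fixed}{a user-supplied threshold in counts.}
#' }
#' Cells strictly above the threshold are flagged `dead`.
#'
#' @param segments a [cell_segments][segment_cells()] after
#'   [transfer_and_integrate()], or a data.frame with a `sum_<rh_channel>`
#'   column.
#' @param rh_channel Rh channel label, default `"103Rh"`.
#' @param method `"otsu"`, `"mad"` or `"fixed"`.
#' @param threshold threshold in counts for `method = "fixed"`.
#' @return the input with a logical `dead` column added to its table.
#' @export
flag_dead_cells <- function(segments, rh_channel = "103Rh",
                            method = c("otsu", "mad", "fixed"),
                            threshold = NULL) {
  method <- match.arg(method)
  tab <- if (inherits(segments, "cell_segments")) segments$table else segments
  col <- paste0("sum_", rh_channel)
  if (!col %in% names(tab))
    stop("no Rh sums (column ", col, ") present", call. = FALSE)
  rh <- tab[[col]]
  thr <- switch(method,
    fixed = {
      if (is.null(threshold)) stop("method='fixed' needs a threshold",
                                   call. = FALSE)
      threshold
    },
    mad = stats::median(rh) + 5 * stats::mad(rh),
    otsu = {
      if (all(rh == 0)) {
        warning("all-zero Rh channel; no cells flagged", call. = FALSE)
        Inf
      } else if (length(unique(rh)) == 1L) {
        Inf  # constant non-zero: no separable modes
      } else expm1(otsu_1d(log1p(rh)))  # log scale: Rh sums span decades
    })
  tab$dead <- rh > thr
  if (inherits(segments, "cell_segments")) {
    segments$table <- tab
    segments$dead_threshold <- thr
    segments
  } else tab
}

# 1-D Otsu: threshold maximising between-class variance of a histogram
otsu_1d <- function(x, n_bins = 256L) {
  br <- seq(min(x), max(x), length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  # maximal sb plateaus across empty gaps; split at the plateau midpoint
  best <- which(sb >= max(sb) - 1e-9 * max(sb))
  k <- best[ceiling(length(best) / 2)]
  (br[k] + br[k + 1L]) / 2
}

#' Quartile summary of a per-cell mass population
#'
#' Summarises a per-cell mass sample the way single-cell elemental studies
#' report populations: n, mean, median and the 25-75 percentile band.
#' Quantiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7), so `c(1, 2, 3, 4)` gives q25 = 1.75,
#' median = 2.5, q75 = 3.25; the convention matters when comparing printed
#' percentile ranges.
#'
#' @param masses numeric vector, fg per cell; non-empty.
#' @param label sample name.
#' @return Object of class `population_summary` (also a one-row list):
#'   `label`, `n`, `mean`, `median`, `q25`, `q75`, `min`, `max`.
#' @export
population_summary <- function(masses, label = "sample") {
  if (length(masses) == 0L) stop("empty mass list", call. = FALSE)
  q <- stats::quantile(masses, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(label = label, n = length(masses), mean = mean(masses),
                 median = q[2], q25 = q[1], q75 = q[3],
                 min = min(masses), max = max(masses)),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, median %.3g fg (25-75%%: %.3g-%.3g), mean %.3g\n",
              x$label, x$n, x$median, x$q25, x$q75, x$mean))
  invisible(x)
}

#' @export
as.data.frame.population_summary <- function(x, ...) {
  data.frame(label = x$label, n = x$n, mean = x$mean, median = x$median,
             q25 = x$q25, q75 = x$q75, min = x$min, max = x$max)
}

#' Welch two-sample t-test on per-cell masses
#'
#' Tests whether the mean element mass per cell differs between two samples
#' without assuming equal variances (Welch statistic, Welch-Satterthwaite
#' degrees of freedom, two-sided p from the t distribution). Thin wrapper
#' over [stats::t.test()] returning the quantities this workflow reports.
#'
#' @param a,b numeric samples, each n >= 2.
#' @return Object of class `welch_result`: `t_statistic`,
#'   `degrees_of_freedom` (real-valued), `p_value`, plus the group means.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs n >= 2", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero variance in both samples", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(t_statistic = unname(ht$statistic),
                 degrees_of_freedom = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_a = mean(a), mean_b = mean(b)),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t = %.4g, df = %.2f, p = %.4g\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value))
  cat(sprintf("  means: %.4g vs %.4g fg\n", x$mean_a, x$mean_b))
  invisible(x)
}

#' Normalise per-cell mass by cell size
#'
#' Removes the trivial size dependence of per-cell element content before
#' comparing populations. Default is mass per equivalent diameter
#' (fg/um); `mode = "volume"` divides by the volume of the sphere with the
#' equivalent diameter (fg/um^3).
#'
#' @param mass_fg mass per cell, fg (vectorised).
#' @param equivalent_diameter_um equivalent diameter, um, > 0.
#' @param mode `"diameter"` (default) or `"volume"`.
#' @return normalised values with a `units` attribute (`"fg/um"` or
#'   `"fg/um^3"`).
#' @examples
#' normalize_by_size(15, 15)                   # 1 fg/um
#' normalize_by_size(15, 15, mode = "volume")  # ~8.49e-3 fg/um^3
#' @export
normalize_by_size <- function(mass_fg, equivalent_diameter_um,
                              mode = c("diameter", "volume")) {
  mode <- match.arg(mode)
  if (any(equivalent_diameter_um <= 0))
    stop("equivalent diameter must be > 0", call. = FALSE)
  out <- switch(mode,
    diameter = mass_fg / equivalent_diameter_um,
    volume = mass_fg / (pi * equivalent_diameter_um^3 / 6))
  structure(out, units = if (mode == "diameter") "fg/um" else "fg/um^3")
}
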