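#' Time-resolved single-cell ICP-MS trace
#'
#' Container for a dwell-resolved count trace with one or more isotope
#' channels, as produced by time-resolved single-cell ICP-MS acquisition.
#' Counts are raw detector counts per dwell (integration window); typical
#' acquisition uses a 3 ms dwell and a 10 uL/min sample flow.
#'
#' @param time_s numeric vector of dwell start times in seconds, strictly
#'   increasing.
#' @param counts integer matrix (or vector for a single channel) of counts per
#'   dwell, one column per isotope channel. Must be non-negative and
#'   integer-valued.
#' @param dwell_s dwell (integration) time in seconds. Default 0.003.
#' @param flow_uL_min sample uptake flow in microlitres per minute.
#'   Default 10.
#' @param channels character vector of isotope labels (e.g. `"195Pt"`). Taken
#'   from `colnames(counts)` when omitted.
#' @return An object of class `time_trace`: a list with elements `time_s`,
#'   `counts` (matrix, one column per channel), `dwell_s`, `flow_uL_min`.
#' @examples
#' tr <- time_trace(seq(0, 0.297, by = 0.003), rpois(100, 2),
#'                  channels = "195Pt")
#' tr
#' @export
time_trace <- function(time_s, counts, dwell_s = 0.003, flow_uL_min = 10,
                       channels = NULL) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1L)
  counts <- as.matrix(counts)
  if (length(time_s) == 0L || nrow(counts) == 0L)
    stop("empty trace", call. = FALSE)
  if (length(time_s) != nrow(counts))
    stop("time_s and counts must have the same length", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be non-negative integers", call. = FALSE)
  if (dwell_s <= 0) stop("dwell_s must be > 0", call. = FALSE)
  if (flow_uL_min <= 0) stop("flow_uL_min must be > 0", call. = FALSE)
  if (!is.null(channels)) {
    if (length(channels) != ncol(counts))
      stop("one channel label per counts column required", call. = FALSE)
    colnames(counts) <- channels
  } else if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("ch", seq_len(ncol(counts)))
  }
  storage.mode(counts) <- "integer"
  structure(list(time_s = as.numeric(time_s), counts = counts,
                 dwell_s = dwell_s, flow_uL_min = flow_uL_min),
            class = "time_trace")
}

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf("time_trace: %d dwells x %d channel(s) [%s]\n",
              nrow(x$counts), ncol(x$counts),
              paste(colnames(x$counts), collapse = ", ")))
  cat(sprintf("  dwell %.4g ms, flow %.4g uL/min, duration %.4g s\n",
              x$dwell_s * 1e3, x$flow_uL_min,
              x$time_s[length(x$time_s)] - x$time_s[1] + x$dwell_s))
  invisible(x)
}

#' @export
length.time_trace <- function(x) nrow(x$counts)

#' Read a time trace from delimited text
#'
#' Expects a header line with a `time_s` column followed by one column per
#' isotope channel. Acquisition metadata may be given as comment lines of the
#' form `# dwell_s: 0.003` and `# flow_uL_min: 10` before the header, or
#' overridden via arguments.
#'
#' @param path file path.
#' @param dwell_s,flow_uL_min metadata overrides; if `NA` the header comments
#'   (or the defaults 0.003 s and 10 uL/min) are used.
#' @param sep field separator, default tab.
#' @return A [time_trace].
#' @export
read_trace <- function(path, dwell_s = NA, flow_uL_min = NA, sep = "\t") {
  head_lines <- readLines(path, n = 50L)
  meta <- list(dwell_s = 0.003, flow_uL_min = 10)
  for (ln in grep("^#", head_lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*([0-9.eE+-]+)", ln))[[1]]
    if (length(m) == 3L && m[2] %in% names(meta))
      meta[[m[2]]] <- as.numeric(m[3])
  }
  if (!is.na(dwell_s)) meta$dwell_s <- dwell_s
  if (!is.na(flow_uL_min)) meta$flow_uL_min <- flow_uL_min
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("no time_s column in ", path, call. = FALSE)
  chans <- setdiff(names(df), "time_s")
  time_trace(df$time_s, as.matrix(df[chans]), dwell_s = meta$dwell_s,
             flow_uL_min = meta$flow_uL_min, channels = chans)
}

#' Write a time trace to delimited text
#'
#' Inverse of [read_trace()]; metadata is stored in `#` comment lines.
#'
#' @param trace a [time_trace].
#' @param path output file path.
#' @param sep field separator, default tab.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, sep = "\t") {
  stopifnot(inherits(trace, "time_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dwell_s: %.10g", trace$dwell_s),
               sprintf("# flow_uL_min: %.10g", trace$flow_uL_min)), con)
  df <- data.frame(time_s = trace$time_s, trace$counts, check.names = FALSE)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
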