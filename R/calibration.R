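# Linear external calibrations: liquid standards (counts vs ug/L) for
# suspension mode, gelatin microdroplet standards (summed counts vs fg) for
# laser-ablation imaging. Both are ordinary least-squares lines via stats::lm.

new_calibration <- function(x, y, xlab, ylab, type, eta = NULL) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("calibration needs >= 2 distinct levels on the x axis", call. = FALSE)
  if (any(x < 0)) stop(xlab, " must be non-negative", call. = FALSE)
  fit <- stats::lm(y ~ x)
  b <- unname(stats::coef(fit)[2])
  if (!is.finite(b)) stop("degenerate calibration fit", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(slope = b,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 x = x, y = y, xlab = xlab, ylab = ylab,
                 eta = eta, type = type, fit = fit),
            class = c(paste0(type, "_calibration"), "icp_calibration"))
}

#' Fit a liquid-standard calibration line
#'
#' Ordinary least-squares line through intensities measured for liquid
#' element standards of known concentration. The slope `b` (counts per ug/L)
#' converts background-subtracted event intensities to concentration
#' equivalents in [event_mass()]. For liquid standards at low uptake flow a
#' transport efficiency of 100\% (`eta = 1`) is the standard assumption.
#'
#' @param concentrations standard concentrations in ug/L, >= 2 distinct
#'   levels, non-negative.
#' @param intensities measured intensities, counts per dwell.
#' @param eta transport efficiency fraction in (0, 1], default 1.
#' @return An `icp_calibration` object with elements `slope` (counts per
#'   ug/L), `intercept`, `r_squared`, `eta`.
#' @examples
#' cal <- fit_liquid_calibration(c(0, 1, 2, 5), c(2, 103, 198, 501))
#' coef(cal)
#' @export
fit_liquid_calibration <- function(concentrations, intensities, eta = 1) {
  if (eta <= 0 || eta > 1) stop("eta must be in (0, 1]", call. = FALSE)
  cal <- new_calibration(concentrations, intensities,
                         "concentration (ug/L)", "intensity (counts)",
                         "liquid", eta = eta)
  if (cal$slope <= 0)
    warning("non-positive calibration slope; calibration unusable for ",
            "quantification", call. = FALSE)
  cal
}

#' Fit a gelatin-microdroplet calibration line
#'
#' Ordinary least-squares line through summed intensities of fully ablated
#' gelatin microdroplet standards against the absolute element amount per
#' droplet (standard concentration times droplet volume; droplets of ~400 pL
#' are typical). The slope (counts per fg) converts per-cell summed
#' intensities to mass in [cell_mass_from_image()].
#'
#' @param amounts_fg element amount per droplet in femtograms, >= 2 distinct
#'   levels, non-negative.
#' @param summed_intensities summed intensity per droplet, counts.
#' @return An `icp_calibration` with `slope` in counts per fg.
#' @examples
#' cal <- fit_droplet_calibration(c(0, 10, 20), c(0, 1000, 2000))
#' cal$slope  # 100 counts/fg
#' @export
fit_droplet_calibration <- function(amounts_fg, summed_intensities) {
  cal <- new_calibration(amounts_fg, summed_intensities,
                         "amount (fg)", "summed intensity (counts)",
                         "droplet")
  if (cal$slope <= 0)
    warning("non-positive calibration slope; calibration unusable for ",
            "quantification", call. = FALSE)
  cal
}

#' Element amount per droplet from concentration and droplet volume
#'
#' @param concentration_ug_L standard concentration in ug/L.
#' @param droplet_volume_pL droplet volume in picolitres, default 400.
#' @return amount in femtograms (1 ug/L over 1 pL = 0.001 fg).
#' @examples
#' droplet_amount_fg(1000)        # 1000 ug/L in 400 pL = 400 fg
#' @export
droplet_amount_fg <- function(concentration_ug_L, droplet_volume_pL = 400) {
  if (any(concentration_ug_L < 0)) stop("negative concentration", call. = FALSE)
  if (droplet_volume_pL <= 0) stop("droplet volume must be > 0", call. = FALSE)
  # ug/L = fg/pL * 1e-3:  1 ug = 1e9 fg, 1 L = 1e12 pL
  concentration_ug_L * 1e-3 * droplet_volume_pL
}

#' @export
print.icp_calibration <- function(x, ...) {
  cat(sprintf("%s calibration: %d level(s)\n", x$type, length(unique(x$x))))
  cat(sprintf("  slope %.6g %s per unit %s, intercept %.6g, r^2 = %.6f\n",
              x$slope, sub(" .*", "", x$ylab), x$xlab, x$intercept,
              x$r_squared))
  if (!is.null(x$eta))
    cat(sprintf("  transport efficiency eta = %.3g\n", x$eta))
  invisible(x)
}

#' @export
coef.icp_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.icp_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  object$intercept + object$slope * newdata
}

#' @export
plot.icp_calibration <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = x$xlab, ylab = x$ylab,
                 main = sprintf("%s calibration (r^2 = %.4f)", x$type,
                                x$r_squared), ...)
  graphics::abline(x$intercept, x$slope, col = "blue3")
  invisible(x)
}

#' @export
residuals.icp_calibration <- function(object, ...) stats::residuals(object$fit)
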