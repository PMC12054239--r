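# Targeted-quantification support: calibration curves, back-calculated
# concentrations, spike recovery, intraday precision (RSD) and
# signal-to-noise detection/quantitation limits.

#' Fit a linear calibration curve
#'
#' Ordinary least squares of peak area on standard concentration. A
#' warning is emitted when `r_squared <= 0.99`, the usual acceptance bar
#' for a quantitative LC-MS assay.
#'
#' @param points data.frame with columns `concentration` and `area`
#'   (at least 3 points with distinct concentrations)
#' @param compound optional compound name
#' @return object of class `calibration_curve`: `compound`, `points`,
#'   `slope`, `intercept`, `r_squared`, `range` (min/max concentration)
#' @export
fit_calibration <- function(points, compound = NA_character_) {
  stopifnot(all(c("concentration", "area") %in% names(points)))
  if (nrow(points) < 3) stop("calibration needs at least 3 points")
  if (length(unique(points$concentration)) < 3) {
    stop("calibration needs at least 3 distinct concentrations")
  }
  fit <- stats::lm(area ~ concentration, data = points)
  r2 <- summary(fit)$r.squared
  if (r2 <= 0.99) {
    warning(sprintf("calibration r-squared %.4f is not above 0.99", r2))
  }
  structure(list(compound = compound, points = points,
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 r_squared = r2,
                 range = range(points$concentration)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("calibration_curve", if (!is.na(x$compound)) paste0("[", x$compound, "]"),
      sprintf(": area = %.4g + %.4g * conc, R2 = %.4f, range %g-%g\n",
              x$intercept, x$slope, x$r_squared, x$range[1], x$range[2]))
  invisible(x)
}

#' Predicted peak area at a concentration
#' @param curve a `calibration_curve`
#' @param concentration numeric
#' @return predicted area
#' @export
predict_area <- function(curve, concentration) {
  curve$intercept + curve$slope * concentration
}

#' Back-calculate concentration from a peak area
#'
#' `(area - intercept) / slope`. Areas mapping outside the calibration
#' range are returned with attribute `extrapolated = TRUE`.
#'
#' @param curve a `calibration_curve` with non-zero slope
#' @param area observed peak area(s)
#' @return concentration(s), with logical attribute `extrapolated`
#' @export
quantify <- function(curve, area) {
  if (curve$slope == 0) stop("calibration slope is zero")
  conc <- (area - curve$intercept) / curve$slope
  extrap <- conc < curve$range[1] | conc > curve$range[2]
  attr(conc, "extrapolated") <- extrap
  conc
}

#' Spike recovery percentage
#'
#' `100 * (spiked - unspiked) / spike_amount`.
#'
#' @param spiked_measured,unspiked_measured measured concentrations
#' @param spike_amount added concentration (> 0)
#' @return recovery in percent
#' @export
recovery_percent <- function(spiked_measured, unspiked_measured,
                             spike_amount) {
  if (any(spike_amount <= 0)) stop("spike amount must be positive")
  100 * (spiked_measured - unspiked_measured) / spike_amount
}

#' Relative standard deviation of QC injections
#'
#' `100 * sd / mean`. A non-positive mean is unphysical for peak areas;
#' the RSD is then computed on the absolute mean with a warning.
#'
#' @param qc_values at least 2 QC measurements
#' @return RSD in percent
#' @export
precision_rsd <- function(qc_values) {
  if (length(qc_values) < 2) stop("RSD needs at least 2 values")
  m <- mean(qc_values)
  if (m == 0) stop("mean of QC values is zero; RSD undefined")
  if (m < 0) {
    warning("non-positive mean; RSD computed on the absolute mean")
    m <- abs(m)
  }
  100 * stats::sd(qc_values) / m
}

#' Detection and quantitation limits from signal-to-noise
#'
#' `LOD = 3 * noise / slope`, `LOQ = 10 * noise / slope` (signal-to-noise
#' thresholds 3 and 10).
#'
#' @param blank_noise_sd noise sd in area units (>= 0)
#' @param slope calibration slope (> 0)
#' @return named numeric vector `c(lod, loq)`
#' @export
lod_loq <- function(blank_noise_sd, slope) {
  if (slope <= 0) stop("slope must be positive")
  if (blank_noise_sd < 0) stop("noise sd must be non-negative")
  c(lod = 3 * blank_noise_sd / slope, loq = 10 * blank_noise_sd / slope)
}
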