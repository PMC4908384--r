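#' Absorption coefficient from transmitted fraction (Beer-Lambert law)
#'
#' @param transmission transmitted fraction, in (0, 1].
#' @param pathlength optical path length in cm (cuvette thickness).
#'
#' @return Absorption coefficient mu_a in 1/cm, `-log(transmission)/pathlength`.
#' @export
beer_lambert_mu <- function(transmission, pathlength = 1) {
  if (any(!is.finite(pathlength)) || any(pathlength <= 0)) {
    stop_invalid("'pathlength' must be positive")
  }
  if (any(!is.finite(transmission)) || any(transmission <= 0)) {
    stop_invalid("transmission <= 0 is outside the measurement range")
  }
  if (any(transmission > 1)) stop_invalid("transmission must be <= 1")
  -log(transmission) / pathlength
}

# Water absorption coefficients in the near infrared, 845-2100 nm, at room
# temperature. Values approximate the standard water-absorption compilations
# (Hale & Querry 1973; Kou, Labrie & Chylek 1993); the 1300 nm node is the
# value conventionally used for pure water at that wavelength (1.34 cm^-1).
# Below ~900 nm water is nearly transparent and hemoglobin dominates in vivo;
# that regime is outside the scope of this table.
.water_absorption <- data.frame(
  wavelength_nm = c(845, 900, 950, 1000, 1100, 1200, 1300, 1400, 1450,
                    1550, 1650, 1750, 1860, 1940, 2000, 2100),
  mu_a_cm1      = c(0.039, 0.068, 0.26, 0.36, 0.17, 1.04, 1.34, 12.5, 29,
                    10.5, 5.0, 6.5, 12.0, 120, 69, 26)
)

#' Bundled near-infrared water absorption spectrum
#'
#' @return An `absorption_spectrum`: data frame with strictly increasing
#'   `wavelength_nm` and non-negative `mu_a_cm1` columns, spanning
#'   845-2100 nm.
#' @export
water_absorption_spectrum <- function() {
  structure(.water_absorption, class = c("absorption_spectrum", "data.frame"))
}

#' Create an absorption spectrum from wavelength / mu_a vectors
#'
#' @param wavelength_nm strictly increasing wavelengths, nm.
#' @param mu_a_cm1 non-negative absorption coefficients, 1/cm.
#' @export
absorption_spectrum <- function(wavelength_nm, mu_a_cm1) {
  if (length(wavelength_nm) != length(mu_a_cm1)) {
    stop_invalid("wavelength and mu_a must have the same length")
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stop_invalid("wavelengths must be strictly increasing")
  }
  if (any(mu_a_cm1 < 0)) stop_invalid("mu_a must be non-negative")
  structure(data.frame(wavelength_nm = wavelength_nm, mu_a_cm1 = mu_a_cm1),
            class = c("absorption_spectrum", "data.frame"))
}

#' Interpolate an absorption spectrum at a wavelength
#'
#' Interpolation is linear in log(mu_a) versus wavelength: water absorption
#' spans several decades across the near infrared and log-linear
#' interpolation stays positive between nodes. Queries at table nodes return
#' the node value exactly; no extrapolation is performed.
#'
#' @param spec an `absorption_spectrum` (default the bundled water table).
#' @param wavelength query wavelength in nm, inside the table range.
#'
#' @return mu_a in 1/cm.
#' @export
lookup_mu_a <- function(spec = water_absorption_spectrum(), wavelength) {
  stopifnot(inherits(spec, "absorption_spectrum"))
  rng <- range(spec$wavelength_nm)
  if (any(wavelength < rng[1] | wavelength > rng[2])) {
    stop_invalid(sprintf("wavelength outside table range [%g, %g] nm",
                         rng[1], rng[2]))
  }
  exp(stats::approx(spec$wavelength_nm, log(spec$mu_a_cm1),
                    xout = wavelength)$y)
}

#' Read an absorption spectrum from CSV
#'
#' Expects columns `wavelength_nm` and `mu_a_cm1`.
#' @param path file path.
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path, header = TRUE)
  if (!all(c("wavelength_nm", "mu_a_cm1") %in% names(d))) {
    stop_invalid("expected columns 'wavelength_nm' and 'mu_a_cm1'")
  }
  absorption_spectrum(d$wavelength_nm, d$mu_a_cm1)
}

#' Fit the ink-concentration absorption calibration line
#'
#' Absorption is varied experimentally by adding India ink to water; mu_a is
#' linear in concentration. Points whose transmission fell outside the
#' spectrometer's measurement range are flagged `extrapolated`: they are
#' excluded from the ordinary least-squares fit and receive predicted values
#' instead. R^2 is computed on the fitted points only.
#'
#' @param concentrations ink concentrations, percent v/v.
#' @param mu_a measured absorption coefficients, 1/cm (ignored for
#'   extrapolated points).
#' @param extrapolated logical mask, `TRUE` for points beyond the measurable
#'   transmission range.
#'
#' @return An `ink_calibration`: list with `concentrations`, `mu_a` (measured
#'   or predicted), `slope` (1/cm per percent), `intercept` (1/cm, the
#'   solvent absorption), `r_squared`, `extrapolated_mask`.
#' @export
fit_ink_calibration <- function(concentrations, mu_a,
                                extrapolated = rep(FALSE, length(mu_a))) {
  stopifnot(length(concentrations) == length(mu_a),
            length(extrapolated) == length(mu_a))
  use <- !extrapolated
  if (sum(use) < 3L) {
    stop_invalid("need at least 3 non-extrapolated points to fit")
  }
  fit <- stats::lm(mu_a[use] ~ concentrations[use])
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # R^2 = 1 - SS_res / SS_tot on the fitted points
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((mu_a[use] - mean(mu_a[use]))^2)
  mu_out <- mu_a
  mu_out[extrapolated] <- slope * concentrations[extrapolated] + intercept
  structure(
    list(concentrations = concentrations, mu_a = mu_out, slope = slope,
         intercept = intercept, r_squared = r2,
         extrapolated_mask = extrapolated),
    class = "ink_calibration"
  )
}

#' @export
print.ink_calibration <- function(x, ...) {
  cat(sprintf(
    "<ink_calibration> mu_a = %.4g * c + %.4g cm^-1 (R^2 = %.6g, %d fitted, %d extrapolated)\n",
    x$slope, x$intercept, x$r_squared,
    sum(!x$extrapolated_mask), sum(x$extrapolated_mask)))
  invisible(x)
}

#' Predict mu_a for an ink concentration
#'
#' @param cal an [fit_ink_calibration()] result.
#' @param concentration percent v/v, non-negative.
#'
#' @return mu_a in 1/cm, `slope * concentration + intercept`.
#' @export
ink_mu_a <- function(cal, concentration) {
  stopifnot(inherits(cal, "ink_calibration"))
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    stop_invalid("'concentration' must be non-negative")
  }
  cal$slope * concentration + cal$intercept
}

#' Read an ink dilution series from CSV
#'
#' Expects columns `concentration_pct`, `transmission`, `pathlength_cm`, and
#' optionally a logical `extrapolated` column. Returns a data frame with a
#' `mu_a_cm1` column computed via [beer_lambert_mu()] for measurable points.
#' @param path file path.
#' @export
read_ink_series_csv <- function(path) {
  d <- utils::read.csv(path, header = TRUE)
  need <- c("concentration_pct", "transmission", "pathlength_cm")
  if (!all(need %in% names(d))) {
    stop_invalid("expected columns ", paste(need, collapse = ", "))
  }
  if (is.null(d$extrapolated)) d$extrapolated <- FALSE
  d$mu_a_cm1 <- NA_real_
  ok <- !d$extrapolated & d$transmission > 0
  d$mu_a_cm1[ok] <- beer_lambert_mu(d$transmission[ok], d$pathlength_cm[ok])
  d
}
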