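#' Thermophysical properties of the absorbing medium
#'
#' Defaults describe water at room temperature, the perilymph analogue used
#' in tank measurements: speed of sound c = 1484 m/s, thermal diffusivity
#' kappa = 1.4e-7 m^2/s, thermal expansion beta = 2.07e-4 1/K, specific heat
#' C_p = 4181 J/(kg K), density 998 kg/m^3. The Grueneisen coefficient
#' defaults to beta * c^2 / C_p (about 0.11 for these values); when all four
#' constituents and `grueneisen` are supplied they must agree within 5%.
#'
#' @param c speed of sound, m/s.
#' @param kappa thermal diffusivity, m^2/s.
#' @param beta volumetric thermal expansion coefficient, 1/K.
#' @param C_p specific heat capacity at constant pressure, J/(kg K).
#' @param rho density, kg/m^3.
#' @param grueneisen dimensionless Grueneisen coefficient; `NULL` computes
#'   beta * c^2 / C_p.
#' @param mu_a absorption coefficient, 1/cm.
#'
#' @return An object of class `medium_properties`.
#' @export
medium_properties <- function(c = 1484, kappa = 1.4e-7, beta = 2.07e-4,
                              C_p = 4181, rho = 998, grueneisen = NULL,
                              mu_a = 1.34) {
  vals <- c(c = c, kappa = kappa, beta = beta, C_p = C_p, rho = rho)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_invalid("all medium properties must be positive and finite")
  }
  if (mu_a < 0) stop_invalid("'mu_a' must be non-negative")
  gamma_c <- beta * c^2 / C_p
  if (is.null(grueneisen)) {
    grueneisen <- gamma_c
  } else if (abs(grueneisen - gamma_c) > 0.05 * gamma_c) {
    stop_invalid(sprintf(
      "grueneisen = %.4g inconsistent with beta*c^2/C_p = %.4g (> 5%%)",
      grueneisen, gamma_c))
  }
  structure(list(c = c, kappa = kappa, beta = beta, C_p = C_p, rho = rho,
                 grueneisen = grueneisen, mu_a = mu_a),
            class = "medium_properties")
}

#' Smallest dimension of the heated volume
#'
#' The heated volume at a fiber tip is bounded radially by the fiber core
#' radius and axially by the optical penetration depth 1/mu_a; the smaller
#' of the two sets both confinement time scales.
#'
#' @param mu_a absorption coefficient, 1/cm (0 means no absorption limit).
#' @param fiber_radius fiber core radius, m.
#'
#' @return delta in metres: `min(1/mu_a, fiber_radius)` with 1/mu_a converted
#'   to metres.
#' @export
smallest_dimension <- function(mu_a, fiber_radius) {
  if (any(mu_a < 0)) stop_invalid("'mu_a' must be non-negative")
  if (any(fiber_radius <= 0)) stop_invalid("'fiber_radius' must be positive")
  pen <- ifelse(mu_a > 0, 1 / (mu_a * 100), Inf)  # 1/cm -> m
  pmin(pen, fiber_radius)
}

#' Thermal confinement limit
#'
#' Maximum pulse duration for which heat conduction out of the heated volume
#' is negligible during the pulse: tau_th = delta^2 / (4 kappa). For a
#' 105 um core fiber in water (delta = 52.5 um, kappa = 1.4e-7 m^2/s) this
#' evaluates to 4.9 ms.
#'
#' @param delta smallest heated dimension, m.
#' @param kappa thermal diffusivity, m^2/s.
#'
#' @return tau_th in seconds.
#' @export
thermal_confinement_limit <- function(delta, kappa = 1.4e-7) {
  if (any(delta <= 0) || any(kappa <= 0)) {
    stop_invalid("'delta' and 'kappa' must be positive")
  }
  delta^2 / (4 * kappa)
}

#' Stress confinement limit
#'
#' Maximum pulse duration for which the stress wave cannot leave the heated
#' volume during the pulse: tau_p = delta / c. For delta = 52.5 um in water
#' (c = 1484 m/s) this is about 35 ns.
#'
#' @param delta smallest heated dimension, m.
#' @param c speed of sound, m/s.
#'
#' @return tau_p in seconds.
#' @export
stress_confinement_limit <- function(delta, c = 1484) {
  if (any(delta <= 0) || any(c <= 0)) {
    stop_invalid("'delta' and 'c' must be positive")
  }
  delta / c
}

#' Classify the confinement regime of a laser pulse
#'
#' Boundaries are inclusive toward the tighter regime: a pulse exactly at
#' tau_p is in stress confinement, one exactly at tau_th in thermal
#' confinement.
#'
#' @param pulse_duration pulse duration, s.
#' @param mu_a absorption coefficient, 1/cm.
#' @param fiber_radius fiber core radius, m.
#' @param medium a [medium_properties()].
#'
#' @return A `confinement_report`: list with `delta` (m), `tau_th` (s),
#'   `tau_p` (s), `regime` (one of "stress", "thermal", "none"),
#'   `mu_a_times_r` and `geometry_class` (see [source_geometry_class()]).
#' @export
classify_regime <- function(pulse_duration, mu_a = 1.34,
                            fiber_radius = 52.5e-6,
                            medium = medium_properties(mu_a = mu_a)) {
  if (pulse_duration <= 0) stop_invalid("'pulse_duration' must be positive")
  delta <- smallest_dimension(mu_a, fiber_radius)
  tau_th <- thermal_confinement_limit(delta, medium$kappa)
  tau_p <- stress_confinement_limit(delta, medium$c)
  regime <- if (pulse_duration <= tau_p) "stress"
            else if (pulse_duration <= tau_th) "thermal"
            else "none"
  geom <- source_geometry_class(mu_a, fiber_radius)
  structure(list(delta = delta, tau_th = tau_th, tau_p = tau_p,
                 regime = regime, mu_a_times_r = geom$mu_a_times_r,
                 geometry_class = geom$geometry_class),
            class = "confinement_report")
}

#' @export
print.confinement_report <- function(x, ...) {
  cat("<confinement_report>\n")
  cat(sprintf("  delta = %.4g m, tau_th = %.4g s, tau_p = %.4g s\n",
              x$delta, x$tau_th, x$tau_p))
  cat(sprintf("  regime: %s confinement; mu_a*r = %.3g (%s geometry)\n",
              x$regime, x$mu_a_times_r, x$geometry_class))
  invisible(x)
}

#' Classify the optoacoustic source geometry
#'
#' The dimensionless product mu_a * r (absorption coefficient times fiber
#' radius, consistent units) separates two asymptotic source shapes: for
#' strong absorption (product >> 1) the heating zone is a thin disk at the
#' fiber tip, for weak absorption (product << 1) an extended cylinder along
#' the beam. Products between 0.1 and 10 are labelled "transition". The
#' measured amplitude-reversal points correspond to products of 0.3 (water,
#' 57.5 1/cm) and about 0.05 (India ink, 8.89 1/cm).
#'
#' @param mu_a absorption coefficient, 1/cm.
#' @param fiber_radius fiber core radius, m.
#'
#' @return List with `mu_a_times_r` and `geometry_class` ("cylinder",
#'   "transition" or "disk").
#' @export
source_geometry_class <- function(mu_a, fiber_radius = 52.5e-6) {
  if (any(mu_a < 0)) stop_invalid("'mu_a' must be non-negative")
  prod <- mu_a * 100 * fiber_radius        # 1/cm -> 1/m, times m
  cls <- ifelse(prod < 0.1, "cylinder", ifelse(prod > 10, "disk", "transition"))
  list(mu_a_times_r = prod, geometry_class = cls)
}
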