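#' Noise specification for synthetic measurements
#'
#' @param sigma additive Gaussian noise standard deviation, in the units of
#'   the signal it is applied to.
#' @param seed integer seed; every generator is a pure function of its
#'   arguments and this seed.
#' @param n_averages number of simulated repetitions averaged together
#'   (hydrophone recordings were averaged over ten thousand laser pulses).
#'
#' @return A `noise_spec`.
#' @export
noise_spec <- function(sigma = 0, seed = 1L, n_averages = 1L) {
  if (sigma < 0) stop_invalid("'sigma' must be non-negative")
  if (n_averages < 1) stop_invalid("'n_averages' must be at least 1")
  structure(list(sigma = sigma, seed = as.integer(seed),
                 n_averages = as.integer(n_averages)),
            class = "noise_spec")
}

# run expr with a private, seeded RNG stream, restoring the caller's RNG
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a photodiode record of a laser pulse
#'
#' The ideal waveform is passed through a first-order low-pass emulating the
#' detector rise time (default 25 ns, an InGaAs photodiode) and additive
#' Gaussian noise is applied. Deterministic for a fixed spec and seed.
#'
#' @param pulse a [pulse_waveform()] (the ideal pulse).
#' @param noise a [noise_spec()]; `sigma` in watts.
#' @param detector_rise detector 10-90% rise time, s.
#'
#' @return A [pulse_waveform()]. Negative noise excursions are kept (the
#'   detector output is a voltage, not a power), so downstream consumers
#'   should treat the record as a measurement; the waveform invariant P >= 0
#'   is relaxed for these records via clipping at write-out only.
#' @export
generate_photodiode_trace <- function(pulse, noise = noise_spec(),
                                      detector_rise = 25e-9) {
  stopifnot(inherits(pulse, "pulse_waveform"), inherits(noise, "noise_spec"))
  P <- as.numeric(first_order_lowpass(pulse$t, pulse$P, detector_rise))
  if (noise$sigma > 0) {
    P <- P + with_seed(noise$seed,
                       stats::rnorm(length(P), sd = noise$sigma))
  }
  pulse_waveform(pulse$t, pmax(P, 0),
                 label = paste0(pulse$meta$label, " [photodiode]"),
                 duration = pulse$meta$duration, energy = pulse$meta$energy)
}

#' Simulate an averaged hydrophone recording
#'
#' Returns the mean of `n_averages` independent noisy replicates of the true
#' trace. Replicates are drawn sequentially from a single seeded stream, so
#' the result is a pure function of (trace, spec). Residual noise scales as
#' `sigma / sqrt(n_averages)`.
#'
#' @param true_trace a [pressure_trace()].
#' @param noise a [noise_spec()]; `sigma` in Pa per single shot.
#'
#' @return A [pressure_trace()] with averaging metadata.
#' @export
generate_hydrophone_recording <- function(true_trace, noise = noise_spec()) {
  stopifnot(inherits(true_trace, "pressure_trace"),
            inherits(noise, "noise_spec"))
  n <- length(true_trace$p)
  p <- true_trace$p
  if (noise$sigma > 0) {
    noise_sum <- with_seed(noise$seed, {
      acc <- numeric(n)
      for (i in seq_len(noise$n_averages)) {
        acc <- acc + stats::rnorm(n, sd = noise$sigma)
      }
      acc
    })
    p <- p + noise_sum / noise$n_averages
  }
  pressure_trace(true_trace$t, p,
                 meta = c(true_trace$meta,
                          list(n_averages = noise$n_averages,
                               noise_sigma = noise$sigma,
                               seed = noise$seed)))
}

#' Generate a synthetic ink dilution series
#'
#' Emulates the spectrometer calibration of an India-ink dilution series:
#' mu_a is linear in concentration, transmission follows Beer-Lambert decay
#' over the cuvette pathlength with multiplicative log-normal noise, and
#' concentrations whose true transmission falls below `t_floor` are flagged
#' as outside the measurement range (to be linearly extrapolated by
#' [fit_ink_calibration()]).
#'
#' @param concentrations percent v/v; default the experimental dilution
#'   series 0.001-5%.
#' @param slope mu_a per percent, 1/cm; default 15.1 (so 5% ink reaches
#'   about 77 1/cm).
#' @param intercept solvent mu_a, 1/cm; default pure water at 1300 nm,
#'   1.34 1/cm.
#' @param pathlength cuvette pathlength, cm.
#' @param noise a [noise_spec()]; `sigma` is the relative (multiplicative)
#'   transmission noise.
#' @param t_floor lowest measurable transmission.
#'
#' @return Data frame with columns `concentration_pct`, `transmission`,
#'   `pathlength_cm`, `extrapolated`, `mu_a_true_cm1`, `mu_a_cm1` (measured;
#'   `NA` where extrapolated).
#' @export
generate_ink_series <- function(concentrations = c(0.001, 0.005, 0.01, 0.05,
                                                   0.1, 0.5, 1, 5),
                                slope = 15.1, intercept = 1.34,
                                pathlength = 1, noise = noise_spec(),
                                t_floor = 1e-4) {
  if (any(concentrations < 0)) {
    stop_invalid("concentrations must be non-negative")
  }
  stopifnot(inherits(noise, "noise_spec"))
  mu_true <- slope * concentrations + intercept
  t_true <- exp(-mu_true * pathlength)
  t_meas <- if (noise$sigma > 0) {
    t_true * with_seed(noise$seed,
                       exp(stats::rnorm(length(t_true), sd = noise$sigma)))
  } else t_true
  extrapolated <- t_true < t_floor
  mu_meas <- rep(NA_real_, length(t_meas))
  mu_meas[!extrapolated] <- beer_lambert_mu(t_meas[!extrapolated], pathlength)
  data.frame(concentration_pct = concentrations,
             transmission = ifelse(extrapolated, NA_real_, t_meas),
             pathlength_cm = pathlength,
             extrapolated = extrapolated,
             mu_a_true_cm1 = mu_true,
             mu_a_cm1 = mu_meas)
}
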