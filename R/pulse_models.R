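#' Laser pulse waveforms
#'
#' A `pulse_waveform` holds a sampled record of optical power versus time on a
#' strictly uniform time grid: the source time-dependence P(t) whose first
#' derivative drives optoacoustic pressure generation. Constructors guarantee
#' the record starts and ends at (numerically) zero power so that the pulse is
#' fully contained in the record and its derivative integrates to zero.
#'
#' @param t numeric vector of sample times in seconds, uniform and increasing.
#' @param P numeric vector of optical power in watts, same length as `t`,
#'   non-negative.
#' @param label short description of the pulse.
#' @param duration nominal pulse duration in seconds (for flat-top pulses the
#'   mid-rise to mid-fall interval; for Gaussian pulses the FWHM).
#' @param energy nominal pulse energy in joules.
#'
#' @return An object of class `pulse_waveform`: a list with elements `t`, `P`
#'   and `meta` (label, nominal duration, nominal energy).
#' @export
pulse_waveform <- function(t, P, label = "pulse", duration = NA_real_,
                           energy = NA_real_) {
  t <- as.numeric(t)
  P <- as.numeric(P)
  if (length(t) != length(P)) {
    stop_invalid("'t' and 'P' must have the same length")
  }
  if (length(t) >= 2L && !is_uniform_grid(t)) {
    stop_invalid("time grid must be uniform and strictly increasing")
  }
  if (any(P < 0)) stop_invalid("optical power must be non-negative")
  structure(
    list(t = t, P = P,
         meta = list(label = label, duration = duration, energy = energy)),
    class = "pulse_waveform"
  )
}

#' @export
print.pulse_waveform <- function(x, ...) {
  m <- pulse_metrics(x)
  cat(sprintf("<pulse_waveform> %s\n", x$meta$label))
  cat(sprintf("  %d samples, dt = %.3g s, span %.3g s\n",
              length(x$t), grid_step(x$t), diff(range(x$t))))
  cat(sprintf("  energy %.4g J, peak %.4g W, FWHM %.4g s\n",
              m$energy, m$peak_power, m$fwhm))
  invisible(x)
}

#' Construct a flat-top (trapezoidal) laser pulse
#'
#' Models the long-pulse regime of diode-pumped stimulation lasers with
#' variable pulse duration (tens of microseconds to tens of milliseconds):
#' linear rise to a constant power plateau, then linear fall. `duration` is
#' measured between the rise and fall midpoints, so pulse energy equals
#' `peak_power * duration` exactly and the separation of the two derivative
#' extrema equals `duration`.
#'
#' @param duration pulse duration in seconds (mid-rise to mid-fall).
#' @param peak_power plateau optical power in watts.
#' @param rise_time,fall_time linear ramp times in seconds; default 1 us.
#' @param dt sample interval in seconds; default `duration/1000`, floored at
#'   1 ns, and never coarser than a tenth of the shortest ramp.
#' @param pre_delay zero-power lead-in before pulse onset, seconds.
#'
#' @return A [pulse_waveform()].
#' @export
make_flat_top <- function(duration, peak_power, rise_time = 1e-6,
                          fall_time = 1e-6, dt = NULL, pre_delay = NULL) {
  if (!is.finite(duration) || duration <= 0) {
    stop_invalid("'duration' must be positive")
  }
  if (!is.finite(peak_power) || peak_power <= 0) {
    stop_invalid("'peak_power' must be positive")
  }
  if (rise_time <= 0 || fall_time <= 0) {
    stop_invalid("rise and fall times must be positive")
  }
  if (duration <= rise_time + fall_time) {
    stop_invalid("'duration' must exceed rise_time + fall_time")
  }
  dt <- dt %||% max(duration / 1000, 1e-9)
  # keep the ramps well resolved so the numerical derivative is grid-stable
  dt <- min(dt, rise_time / 10, fall_time / 10)
  if (duration <= 2 * dt) stop_invalid("'dt' too coarse for this duration")
  pre_delay <- pre_delay %||% max(5e-6, 5 * dt)

  # onset (start of rise) at t = pre_delay; plateau between ramps
  plateau <- duration - (rise_time + fall_time) / 2
  t_end <- pre_delay + rise_time + plateau + fall_time + pre_delay
  t <- seq(0, t_end, by = dt)
  t0 <- pre_delay
  t1 <- t0 + rise_time
  t2 <- t1 + plateau
  t3 <- t2 + fall_time
  P <- numeric(length(t))
  i <- t >= t0 & t < t1
  P[i] <- peak_power * (t[i] - t0) / rise_time
  P[t >= t1 & t <= t2] <- peak_power
  i <- t > t2 & t < t3
  P[i] <- peak_power * (t3 - t[i]) / fall_time
  pulse_waveform(t, P,
                 label = sprintf("flat-top %.3g s @ %.3g W", duration, peak_power),
                 duration = duration, energy = peak_power * duration)
}

#' Construct a Gaussian (nanosecond-regime) laser pulse
#'
#' Models Q-switched/OPO pulses whose duration is fixed at a few nanoseconds.
#' The waveform integrates to `energy` and has full width at half maximum
#' `fwhm`.
#'
#' @param fwhm full width at half maximum in seconds.
#' @param energy pulse energy in joules (0 gives an all-zero record).
#' @param dt sample interval in seconds; default `fwhm/50`, floored at the
#'   resolution limit `fwhm/2`.
#' @param pre_delay zero-power lead-in before the 3-FWHM truncation point,
#'   seconds.
#'
#' @return A [pulse_waveform()].
#' @export
make_gaussian <- function(fwhm, energy, dt = NULL, pre_delay = NULL) {
  if (!is.finite(fwhm) || fwhm <= 0) stop_invalid("'fwhm' must be positive")
  if (!is.finite(energy) || energy < 0) {
    stop_invalid("'energy' must be non-negative")
  }
  dt <- dt %||% (fwhm / 50)
  if (fwhm < 2 * dt) {
    stop_invalid("'fwhm' must be at least 2*dt to be resolved")
  }
  pre_delay <- pre_delay %||% (2 * fwhm)
  half_span <- 3 * fwhm                  # exp(-4 ln2 * 9) ~ 1e-11: effectively 0
  t_end <- pre_delay + 2 * half_span + pre_delay
  t <- seq(0, t_end, by = dt)
  tc <- pre_delay + half_span
  sigma2 <- fwhm^2 / (8 * log(2))
  peak <- if (energy > 0) energy / sqrt(2 * pi * sigma2) else 0
  P <- peak * exp(-(t - tc)^2 / (2 * sigma2))
  pulse_waveform(t, P,
                 label = sprintf("gaussian %.3g s FWHM, %.3g J", fwhm, energy),
                 duration = fwhm, energy = energy)
}

#' Numerical time derivative of pulse power
#'
#' Interior samples use the average of the forward and the backward difference
#' (equivalent to the central difference on a uniform grid); the endpoints use
#' one-sided differences so the derivative record has the same length and grid
#' as the waveform.
#'
#' @param w a [pulse_waveform()] with at least 3 samples.
#'
#' @return An object of class `derivative_trace`: list with `t` (s), `dPdt`
#'   (W/s), `max_dPdt` and `min_dPdt` (the signed extrema).
#' @export
power_derivative <- function(w) {
  stopifnot(inherits(w, "pulse_waveform"))
  n <- length(w$t)
  if (n < 3L) stop_invalid("need at least 3 samples")
  if (!is_uniform_grid(w$t)) stop_invalid("time grid must be uniform")
  dt <- grid_step(w$t)
  P <- w$P
  d <- numeric(n)
  d[2:(n - 1)] <- (P[3:n] - P[1:(n - 2)]) / (2 * dt)
  d[1] <- (P[2] - P[1]) / dt
  d[n] <- (P[n] - P[n - 1]) / dt
  structure(list(t = w$t, dPdt = d, max_dPdt = max(d), min_dPdt = min(d)),
            class = "derivative_trace")
}

#' Summary metrics of a laser pulse
#'
#' @param w a [pulse_waveform()].
#'
#' @return List with `energy` (J, trapezoid rule), `peak_power` (W), `fwhm`
#'   (s, measured at half of peak power with linear interpolation between the
#'   bracketing samples; `NA` with a warning for an all-zero waveform),
#'   `max_dPdt` and `min_dPdt` (W/s).
#' @export
pulse_metrics <- function(w) {
  stopifnot(inherits(w, "pulse_waveform"))
  energy <- trapz(w$t, w$P)
  peak <- max(w$P)
  if (peak <= 0) {
    warning("all-zero waveform: FWHM undefined", call. = FALSE)
    return(list(energy = 0, peak_power = 0, fwhm = NA_real_,
                max_dPdt = 0, min_dPdt = 0))
  }
  half <- peak / 2
  above <- w$P >= half
  i1 <- which(above)[1]
  i2 <- which(above)[sum(above)]
  # linear interpolation to the half-power crossings
  t_lo <- if (i1 == 1L) w$t[1] else {
    w$t[i1 - 1] + (half - w$P[i1 - 1]) / (w$P[i1] - w$P[i1 - 1]) *
      (w$t[i1] - w$t[i1 - 1])
  }
  t_hi <- if (i2 == length(w$P)) w$t[i2] else {
    w$t[i2] + (w$P[i2] - half) / (w$P[i2] - w$P[i2 + 1]) *
      (w$t[i2 + 1] - w$t[i2])
  }
  d <- power_derivative(w)
  list(energy = energy, peak_power = peak, fwhm = t_hi - t_lo,
       max_dPdt = d$max_dPdt, min_dPdt = d$min_dPdt)
}

#' Convert a period to the corresponding frequency
#'
#' The onset and offset pressure pulses of a flat-top laser pulse form one
#' excitation period; its reciprocal is the equivalent acoustic frequency
#' (e.g. an 80 us pulse corresponds to 12.5 kHz, inside the most sensitive
#' region of the guinea-pig audiogram).
#'
#' @param interval period in seconds, positive.
#'
#' @return Frequency in Hz.
#' @export
period_to_frequency <- function(interval) {
  if (any(!is.finite(interval)) || any(interval <= 0)) {
    stop_invalid("'interval' must be positive")
  }
  1 / interval
}

#' Read / write pulse waveforms as two-column CSV
#'
#' The on-disk format is a header line `time_s,power_W` followed by one row
#' per sample, decimal point always `.` regardless of locale.
#'
#' @param path file path.
#' @param w a [pulse_waveform()] (writer only).
#' @param label label for the ingested waveform.
#' @param detector_rise optional photodiode rise-time constant in seconds;
#'   when given, the waveform is passed through a first-order low-pass with
#'   time constant `detector_rise / log(9)` (10-90% rise time equal to
#'   `detector_rise`), emulating detector-limited acquisition. Use `NULL`
#'   (default) for no filtering.
#'
#' @return `read_pulse_csv` returns a [pulse_waveform()]; `write_pulse_csv`
#'   returns `path` invisibly.
#' @export
read_pulse_csv <- function(path, label = basename(path), detector_rise = NULL) {
  d <- utils::read.csv(path, header = TRUE)
  if (!all(c("time_s", "power_W") %in% names(d))) {
    stop_invalid("expected columns 'time_s' and 'power_W'")
  }
  P <- d$power_W
  if (!is.null(detector_rise)) {
    P <- first_order_lowpass(d$time_s, P, detector_rise)
  }
  pulse_waveform(d$time_s, pmax(P, 0), label = label)
}

#' @rdname read_pulse_csv
#' @export
write_pulse_csv <- function(w, path) {
  stopifnot(inherits(w, "pulse_waveform"))
  utils::write.csv(data.frame(time_s = w$t, power_W = w$P), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# first-order low-pass with 10-90% rise time 'rise' (tau = rise / ln 9),
# implemented as an exact exponential recursion on the uniform grid
first_order_lowpass <- function(t, x, rise) {
  tau <- rise / log(9)
  a <- exp(-grid_step(t) / tau)
  stats::filter(x * (1 - a), filter = a, method = "recursive",
                init = x[1])[seq_along(x)]
}
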