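#' Compound-action-potential surrogate response
#'
#' Transforms a pressure trace into a CAP-like response trace. The auditory
#' nerve population responds to either polarity of basilar-membrane
#' deflection (CAP generation is non-linearly rectifying) and integrates
#' over a prolonged window, which acts as a low-pass filter: separate onset
#' and offset pressure pulses merge into a single neural response when they
#' fall within the integration window. The pipeline is
#'
#' 1. band-pass filtering (recording chain; default 5 Hz - 5 kHz,
#'    6th-order Butterworth applied as cascaded high- and low-pass halves),
#' 2. full-wave rectification,
#' 3. convolution with a unit-area alpha kernel
#'    `k(t) = t / tau^2 * exp(-t / tau)` of time constant
#'    `integration_time`.
#'
#' The input is resampled internally to 102 kHz (the acquisition rate the
#' stage is designed around) before filtering.
#'
#' @param p a [pressure_trace()] spanning the pulse plus at least five
#'   integration times.
#' @param integration_time alpha-kernel time constant, s; default 0.8 ms, chosen so that the simulated merge threshold falls near the observed 1 ms boundary.
#' @param band band-pass corner frequencies `c(low, high)` in Hz.
#'
#' @return A `cap_trace`: list with `t` (s), `v` (response, arbitrary
#'   units), `peaks` (data frame from [detect_response_peaks()]),
#'   `n1p1_amplitude` (height of the first response peak above the
#'   pre-response baseline; the surrogate is unipolar after rectification,
#'   so the N1-P1 excursion collapses to this single height) and
#'   `integration_time`.
#' @export
cap_response <- function(p, integration_time = 8e-4, band = c(5, 5000)) {
  stopifnot(inherits(p, "pressure_trace"))
  if (integration_time <= 0) {
    stop_invalid("'integration_time' must be positive")
  }
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1]) {
    stop_invalid("'band' must be increasing positive corner frequencies")
  }
  fs <- 1.02e5
  span <- p$t[length(p$t)] - p$t[1]
  if (span < 5 * integration_time) {
    stop_invalid("trace must span at least 5 integration times")
  }
  tt <- seq(p$t[1], p$t[length(p$t)], by = 1 / fs)
  x <- stats::approx(p$t, p$p, xout = tt)$y
  if (all(x == 0)) {
    v <- numeric(length(tt))
  } else {
    # 6th-order band-pass as 3rd-order high-pass + 3rd-order low-pass;
    # the cascade stays numerically well conditioned at a 5 Hz corner
    lp <- signal::butter(3, min(band[2] / (fs / 2), 0.99), type = "low")
    hp <- signal::butter(3, band[1] / (fs / 2), type = "high")
    x <- signal::filtfilt(lp, signal::filtfilt(hp, x))
    x <- abs(x)                          # full-wave rectification
    tau <- integration_time
    tk <- seq(0, 10 * tau, by = 1 / fs)
    kern <- tk / tau^2 * exp(-tk / tau)
    kern <- kern / sum(kern * (1 / fs))  # unit area in continuous time
    v <- fft_convolve(x, kern)[seq_along(tt)] / fs
  }
  pk <- detect_peaks_internal(tt, v, threshold_frac = 0.3,
                              min_sep = integration_time)
  n1p1 <- if (nrow(pk) > 0) pk$amplitude[1] else 0
  structure(list(t = tt, v = v, peaks = pk, n1p1_amplitude = n1p1,
                 integration_time = integration_time, band = band),
            class = "cap_trace")
}

#' @export
print.cap_trace <- function(x, ...) {
  cat(sprintf("<cap_trace> %d samples, %d peak(s), N1P1 = %.3g a.u.\n",
              length(x$t), nrow(x$peaks), x$n1p1_amplitude))
  invisible(x)
}

# local maxima above threshold_frac * global max, with minimum separation
detect_peaks_internal <- function(t, v, threshold_frac, min_sep) {
  empty <- data.frame(time = numeric(0), amplitude = numeric(0),
                      polarity = integer(0))
  n <- length(v)
  if (n < 3L) return(empty)
  vmax <- max(v)
  if (vmax <= 0) return(empty)
  thr <- threshold_frac * vmax
  cand <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n] &
                  v[2:(n - 1)] >= thr) + 1L
  if (length(cand) == 0L) return(empty)
  # greedy pruning, highest peaks first, enforcing minimum separation
  keep <- integer(0)
  for (i in cand[order(v[cand], decreasing = TRUE)]) {
    if (all(abs(t[i] - t[keep]) >= min_sep)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  data.frame(time = t[keep], amplitude = v[keep],
             polarity = rep(1L, length(keep)))
}

#' Detect response peaks in a CAP-surrogate trace
#'
#' Local maxima above a fraction of the global maximum, separated by at
#' least the integration time (closer secondary maxima are considered part
#' of the same response event).
#'
#' @param cap a [cap_response()] result.
#' @param threshold_frac detection threshold as a fraction of the global
#'   maximum, in (0, 1).
#'
#' @return Data frame with columns `time`, `amplitude`, `polarity`.
#' @export
detect_response_peaks <- function(cap, threshold_frac = 0.3) {
  stopifnot(inherits(cap, "cap_trace"))
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    stop_invalid("'threshold_frac' must be in (0, 1)")
  }
  detect_peaks_internal(cap$t, cap$v, threshold_frac,
                        min_sep = cap$integration_time)
}

#' Minimum pulse duration with separable onset and offset responses
#'
#' Bisects over flat-top pulse durations, feeding an idealized bipolar
#' pressure pattern (a compression at onset, a rarefaction at offset, as the
#' forward model produces) through the CAP-surrogate pipeline, and returns
#' the smallest duration for which two response peaks are detected. With
#' default parameters the threshold falls near 1 ms, matching the
#' observation that separate onset and offset CAPs only appear for pulses
#' longer than about 1 ms while hydrophone traces resolve both at all
#' durations.
#'
#' @param integration_time alpha-kernel time constant, s.
#' @param band band-pass corners, Hz.
#' @param lower,upper bisection bracket on pulse duration, s.
#' @param tol convergence tolerance, s; default one 102 kHz sample.
#'
#' @return Threshold duration in seconds.
#' @export
merge_threshold <- function(integration_time = 8e-4, band = c(5, 5000),
                            lower = 5e-5, upper = 2e-2, tol = 1e-5) {
  if (integration_time <= 0) {
    stop_invalid("'integration_time' must be positive")
  }
  two_peaks <- function(dur) {
    nrow(detect_response_peaks(
      cap_response(bipolar_test_trace(dur), integration_time, band))) >= 2L
  }
  if (two_peaks(lower)) return(lower)
  if (!two_peaks(upper)) {
    stop_invalid("bisection bracket does not contain the merge threshold")
  }
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (two_peaks(mid)) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}

# idealized onset/offset pressure pattern for threshold analysis: narrow
# opposite-polarity gaussian pulses separated by the flat-top duration
bipolar_test_trace <- function(duration, fs = 1.02e6) {
  t0 <- 2e-3
  t_end <- t0 + duration + 1e-2
  t <- seq(0, t_end, by = 1 / fs)
  width <- 2e-5
  p <- exp(-(t - t0)^2 / (2 * width^2)) -
    exp(-(t - (t0 + duration))^2 / (2 * width^2))
  pressure_trace(t, p)
}

#' Write a CAP-surrogate trace to CSV / its peaks to JSON
#'
#' @param cap a `cap_trace`.
#' @param path output file path.
#' @export
write_cap_csv <- function(cap, path) {
  stopifnot(inherits(cap, "cap_trace"))
  utils::write.csv(data.frame(time_s = cap$t, response_au = cap$v), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cap_csv
#' @export
write_cap_peaks_json <- function(cap, path) {
  stopifnot(inherits(cap, "cap_trace"))
  jsonlite::write_json(cap$peaks, path, dataframe = "rows", digits = NA)
  invisible(path)
}
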