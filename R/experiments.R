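#' Default configuration for the parameter-sweep experiments
#'
#' Values follow the experimental setup the package models: 105 um core
#' fiber (52.5 um radius), hydrophone-like field point on axis 0.1 mm beyond
#' the tip, 100 kHz amplifier bandwidth, 102 kHz sampling, water-like medium,
#' flat-top rise/fall 1 us, 6 uJ reference pulse energy, 150 mW reference
#' peak power, averaging over ten thousand pulses with single-shot noise of
#' 10% of the reference peak pressure ("auto").
#'
#' @param ... named overrides of any config entry.
#' @return A named list.
#' @export
default_experiment_config <- function(...) {
  cfg <- list(
    energy_J = 6e-6,
    peak_power_W = 0.15,
    fiber_radius_m = 52.5e-6,
    mu_a_cm1 = 10,
    distance_m = 1e-4,
    lateral_offset_m = 0,
    rise_time_s = 1e-6,
    fall_time_s = 1e-6,
    gaussian_threshold_s = 1e-5,   # durations below this use a Gaussian pulse
    bandwidth_hz = 1e5,
    sampling_hz = 1.02e5,
    voxels_per_scale = 10,
    noise_sigma_pa = "auto",       # 10% of the reference single-shot peak
    n_averages = 10000L,
    detect_k = 3,                  # detectability: k * residual noise
    integration_time_s = 8e-4,
    cap_band_hz = c(5, 5000),
    seed = 1L,
    medium = medium_properties()
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    stop_invalid("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  utils::modifyList(cfg, over)
}

check_config <- function(config) {
  need <- names(default_experiment_config())
  missing <- setdiff(need, names(config))
  if (length(missing) > 0) {
    stop_invalid("missing config key(s): ", paste(missing, collapse = ", "))
  }
  config
}

# build the pulse for a sweep condition: Gaussian in the nanosecond regime
# (OPO laser), flat-top otherwise (long-pulse laser)
sweep_pulse <- function(duration, energy = NULL, peak_power = NULL, config) {
  if (duration < config$gaussian_threshold_s) {
    if (is.null(energy)) energy <- peak_power * duration
    make_gaussian(fwhm = duration, energy = energy)
  } else {
    if (is.null(peak_power)) peak_power <- energy / duration
    make_flat_top(duration, peak_power, rise_time = config$rise_time_s,
                  fall_time = config$fall_time_s)
  }
}

# simulate one sweep condition end to end; returns the result row plus the
# traces (raw solver output and measurement-chain output)
simulate_condition <- function(pulse, config, mu_a = config$mu_a_cm1,
                               keep_traces = FALSE) {
  config <- check_config(config)
  m <- pulse_metrics(pulse)
  source <- build_heating_source(pulse_energy = m$energy,
                                 fiber_radius = config$fiber_radius_m,
                                 mu_a = mu_a,
                                 voxels_per_scale = config$voxels_per_scale)
  fp <- field_point(config$distance_m, config$lateral_offset_m)
  raw <- suppressWarnings(
    pressure_at_point(source, pulse, fp, config$medium))
  # pad (at the filter's internal rate) so the 102 kHz record and the CAP
  # stage have a baseline before and after the event
  meas <- apply_measurement_chain(raw, config$bandwidth_hz,
                                  config$sampling_hz,
                                  pad = c(2e-3, 4e-3))
  cap <- cap_response(meas, config$integration_time_s, config$cap_band_hz)
  interval <- abs(raw$t[which.max(raw$p)] - raw$t[which.min(raw$p)])
  regime <- classify_regime(pulse$meta$duration, mu_a,
                            config$fiber_radius_m, config$medium)
  row <- data.frame(
    duration_s = pulse$meta$duration,
    pulse_type = if (grepl("gaussian", pulse$meta$label)) "gaussian"
                 else "flat_top",
    energy_J = m$energy,
    peak_power_W = m$peak_power,
    max_dPdt_W_s = m$max_dPdt,
    mu_a_cm1 = mu_a,
    peak_pressure_Pa = raw$peak_abs,
    peak_measured_Pa = meas$peak_abs,
    spl_raw_db_re_1uPa = spl_re_1uPa(raw$peak_abs),
    spl_db_re_1uPa = spl_re_1uPa(meas$peak_abs),
    n1p1_au = cap$n1p1_amplitude,
    n_cap_peaks = nrow(cap$peaks),
    onset_offset_interval_s = interval,
    regime = regime$regime,
    geometry_class = regime$geometry_class,
    near_field = isTRUE(raw$meta$near_field)
  )
  if (keep_traces) list(row = row, raw = raw, meas = meas, cap = cap)
  else row
}

# single-shot noise sigma in Pa: configured value, or 10% of the raw peak of
# the reference condition (6 uJ, 30 us flat-top at the config geometry)
resolve_noise_sigma <- function(config) {
  if (!identical(config$noise_sigma_pa, "auto")) {
    return(as.numeric(config$noise_sigma_pa))
  }
  ref <- simulate_condition(
    sweep_pulse(30e-6, energy = 6e-6, config = config), config)
  0.1 * ref$peak_pressure_Pa
}

finish_sweep <- function(rows, sweep_name, config, sigma_single) {
  res <- do.call(rbind, rows)
  res <- cbind(sweep = sweep_name, res)
  residual <- sigma_single / sqrt(config$n_averages)
  res$detectable <- res$peak_pressure_Pa >= config$detect_k * residual
  attr(res, "noise") <- list(sigma_single_pa = sigma_single,
                             residual_pa = residual,
                             n_averages = config$n_averages)
  class(res) <- c("sweep_result", "data.frame")
  res
}

#' Constant-energy pulse-duration sweep
#'
#' Simulates peak pressure versus pulse duration at fixed pulse energy
#' (default 6 uJ, durations from the nanosecond to the 200 us regime, so
#' peak power and the maximum power derivative fall as duration grows).
#' The result carries a linear regression of raw peak pressure on the
#' maximum power derivative over the flat-top conditions as attribute
#' `derivative_fit` (the mechanism predicts proportionality).
#'
#' @param energy pulse energy, J.
#' @param durations sorted pulse durations, s.
#' @param config a [default_experiment_config()] list.
#'
#' @return A `sweep_result` data frame, one row per duration.
#' @export
sweep_constant_energy <- function(energy = 6e-6,
                                  durations = c(5e-9, 1e-5, 2e-5, 3e-5,
                                                5e-5, 1e-4, 2e-4),
                                  config = default_experiment_config()) {
  config <- check_config(config)
  if (is.unsorted(durations)) stop_invalid("'durations' must be sorted")
  rows <- lapply(durations, function(d) {
    simulate_condition(sweep_pulse(d, energy = energy, config = config),
                       config)
  })
  res <- finish_sweep(rows, "constant_energy", config,
                      resolve_noise_sigma(config))
  ft <- res[res$pulse_type == "flat_top", ]
  if (nrow(ft) >= 3) {
    attr(res, "derivative_fit") <-
      stats::lm(peak_pressure_Pa ~ max_dPdt_W_s, data = ft)
  }
  res
}

#' Constant-peak-power pulse-duration sweep
#'
#' Simulates pressure versus pulse duration at fixed plateau power (default
#' 150 mW; pulse energy grows with duration). Since the maximum power
#' derivative is set by the fixed rise time and plateau power, the onset
#' pressure amplitude is expected to be nearly constant, while the interval
#' between the onset and offset pressure events tracks the pulse duration
#' exactly.
#'
#' @param peak_power plateau power, W.
#' @param durations sorted pulse durations, s.
#' @inheritParams sweep_constant_energy
#' @return A `sweep_result` data frame.
#' @export
sweep_constant_power <- function(peak_power = 0.15,
                                 durations = c(1e-5, 4e-5, 1e-4, 4e-4,
                                               1e-3, 2e-3, 5e-3, 1e-2),
                                 config = default_experiment_config()) {
  config <- check_config(config)
  if (is.unsorted(durations)) stop_invalid("'durations' must be sorted")
  rows <- lapply(durations, function(d) {
    simulate_condition(
      sweep_pulse(d, peak_power = peak_power, config = config), config)
  })
  finish_sweep(rows, "constant_power", config, resolve_noise_sigma(config))
}

#' Absorption-coefficient sweep
#'
#' Simulates peak pressure at the fixed field point as a function of the
#' medium absorption coefficient (experimentally varied via wavelength, for
#' water, or India-ink concentration at fixed wavelength). The location of
#' the amplitude maximum over the grid and the corresponding mu_a * r
#' product are attached as attribute `reversal` as a diagnostic: the
#' measured reversal points (57.5 and 8.89 1/cm) involve source-geometry
#' physics beyond this linear model and are reported, not asserted.
#'
#' @param mu_a_grid sorted positive absorption coefficients, 1/cm.
#' @param duration pulse duration, s; default the 5 ns OPO pulse used for
#'   the absorption studies.
#' @param energy pulse energy, J.
#' @inheritParams sweep_constant_energy
#' @return A `sweep_result` data frame.
#' @export
sweep_absorption <- function(mu_a_grid = c(1.34, 2, 3.5, 5, 8.89, 15, 25,
                                           40, 57.5, 77, 100, 124),
                             duration = 5e-9, energy = 6e-6,
                             config = default_experiment_config()) {
  config <- check_config(config)
  if (any(mu_a_grid <= 0) || is.unsorted(mu_a_grid)) {
    stop_invalid("'mu_a_grid' must be positive and sorted")
  }
  pulse <- sweep_pulse(duration, energy = energy, config = config)
  rows <- lapply(mu_a_grid, function(mu) {
    simulate_condition(pulse, config, mu_a = mu)
  })
  res <- finish_sweep(rows, "absorption", config, resolve_noise_sigma(config))
  i <- which.max(res$peak_pressure_Pa)
  j <- which.max(res$peak_measured_Pa)
  attr(res, "reversal") <- list(
    mu_a_argmax_cm1 = res$mu_a_cm1[i],
    mu_a_argmax_measured_cm1 = res$mu_a_cm1[j],
    mu_a_times_r_at_argmax =
      source_geometry_class(res$mu_a_cm1[i], config$fiber_radius_m)$mu_a_times_r)
  res
}

#' Run all parameter studies and write a report bundle
#'
#' Executes the constant-energy, constant-power and absorption sweeps, the
#' ink-calibration round trip on seeded synthetic data, and the confinement
#' report for the default geometry; writes one CSV per sweep plus a JSON
#' summary of the headline quantities to `out_dir`. Reruns with the same
#' configuration produce identical files.
#'
#' @param config a config list from [default_experiment_config()], or the
#'   path to a YAML file with (a subset of) its keys.
#' @param out_dir output directory, created if needed.
#'
#' @return Invisibly, a list with the three sweeps, the ink calibration and
#'   the summary list.
#' @export
run_all <- function(config = default_experiment_config(),
                    out_dir = "optocochlea-results") {
  if (is.character(config)) {
    over <- yaml::read_yaml(config)
    config <- do.call(default_experiment_config, over)
  }
  config <- check_config(config)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop_invalid("cannot create output directory: ", out_dir)
    }
  }
  t_start <- Sys.time()
  message("optocochlea run_all: seed = ", config$seed)

  ce <- sweep_constant_energy(config = config)
  cp <- sweep_constant_power(config = config)
  ab <- sweep_absorption(config = config)
  for (x in list(list(ce, "sweep_constant_energy.csv"),
                 list(cp, "sweep_constant_power.csv"),
                 list(ab, "sweep_absorption.csv"))) {
    utils::write.csv(as.data.frame(x[[1]]), file.path(out_dir, x[[2]]),
                     row.names = FALSE, quote = FALSE)
  }

  ink <- generate_ink_series(noise = noise_spec(sigma = 0.005,
                                                seed = config$seed))
  cal <- fit_ink_calibration(ink$concentration_pct,
                             ifelse(ink$extrapolated, 0, ink$mu_a_cm1),
                             ink$extrapolated)
  utils::write.csv(ink, file.path(out_dir, "ink_series.csv"),
                   row.names = FALSE, quote = FALSE)

  conf <- classify_regime(30e-6, config$mu_a_cm1, config$fiber_radius_m,
                          config$medium)
  ref <- simulate_condition(
    sweep_pulse(30e-6, energy = config$energy_J, config = config), config)
  fit <- attr(ce, "derivative_fit")
  summary <- list(
    seed = config$seed,
    tau_th_s = conf$tau_th,
    tau_p_s = conf$tau_p,
    regime_30us = conf$regime,
    reference_peak_pressure_Pa = ref$peak_pressure_Pa,
    reference_spl_db_re_1uPa = ref$spl_db_re_1uPa,
    derivative_fit_r_squared =
      if (!is.null(fit)) summary(fit)$r.squared else NA,
    constant_power_onset_spread =
      diff(range(cp$peak_pressure_Pa)) / max(cp$peak_pressure_Pa),
    absorption_reversal = attr(ab, "reversal"),
    ink_slope_cm1_per_pct = cal$slope,
    ink_intercept_cm1 = cal$intercept,
    ink_r_squared = cal$r_squared,
    merge_threshold_s = merge_threshold(config$integration_time_s,
                                        config$cap_band_hz),
    runtime_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    r_version = R.version.string
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("run_all finished in %.1f s", summary$runtime_s))
  invisible(list(constant_energy = ce, constant_power = cp,
                 absorption = ab, ink_calibration = cal, summary = summary))
}
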