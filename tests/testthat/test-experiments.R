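# sweep-level tests use reduced duration / mu_a grids; the physics and the
# full pipeline per condition are identical to the defaults

test_that("constant-energy sweep: amplitude falls with duration and tracks
          the power derivative", {
  ce <- sweep_constant_energy(durations = c(5e-9, 1e-5, 3e-5, 1e-4, 2e-4),
                              config = test_config())
  expect_true(all(diff(ce$peak_pressure_Pa) < 0))
  expect_true(all(diff(ce$peak_measured_Pa) < 0))
  fit <- attr(ce, "derivative_fit")
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_true(all(ce$detectable))
  expect_true(all(ce$spl_raw_db_re_1uPa > 100))
  expect_error(sweep_constant_energy(durations = c(1e-4, 1e-5),
                                     config = test_config()), "sorted")
})

test_that("constant-power sweep: constant onset, interval equals duration,
          CAP merging", {
  cp <- sweep_constant_power(durations = c(1e-5, 4e-5, 1e-4, 2e-3),
                             config = test_config())
  spread <- diff(range(cp$peak_pressure_Pa)) / max(cp$peak_pressure_Pa)
  expect_lt(spread, 0.05)
  expect_equal(cp$onset_offset_interval_s, cp$duration_s,
               tolerance = 1e-3)
  expect_equal(cp$n_cap_peaks[cp$duration_s == 1e-4], 1)
  expect_equal(cp$n_cap_peaks[cp$duration_s == 2e-3], 2)
  expect_true(all(cp$spl_raw_db_re_1uPa > 100))
  # regimes follow the 4.9 ms thermal boundary
  expect_true(all(cp$regime == "thermal"))
})

test_that("the sweeps agree at their shared condition (150 mW, 40 us)", {
  cfg <- test_config()
  ce <- sweep_constant_energy(energy = 6e-6, durations = 4e-5, config = cfg)
  cp <- sweep_constant_power(peak_power = 0.15, durations = 4e-5,
                             config = cfg)
  expect_equal(ce$peak_power_W, 0.15, tolerance = 1e-9)
  expect_equal(cp$energy_J, 6e-6, tolerance = 1e-9)
  expect_equal(ce$peak_pressure_Pa, cp$peak_pressure_Pa, tolerance = 1e-12)
  expect_equal(ce$n1p1_au, cp$n1p1_au, tolerance = 1e-12)
})

test_that("absorption sweep reports the reversal diagnostic", {
  ab <- sweep_absorption(mu_a_grid = c(1.34, 3.5, 8.89, 25, 57.5),
                         config = test_config())
  # low-absorption branch: amplitude grows with mu_a
  expect_true(all(diff(ab$peak_pressure_Pa) > 0))
  expect_equal(round(source_geometry_class(57.5, 52.5e-6)$mu_a_times_r, 1),
               0.3)
  rev <- attr(ab, "reversal")
  expect_true(is.numeric(rev$mu_a_argmax_cm1))
  expect_true(is.numeric(rev$mu_a_times_r_at_argmax))
  one <- sweep_absorption(mu_a_grid = 8.89, config = test_config())
  expect_equal(attr(one, "reversal")$mu_a_argmax_cm1, 8.89)
  expect_error(sweep_absorption(mu_a_grid = c(-1, 2),
                                config = test_config()), "positive")
})

test_that("sweeps are deterministic given the configuration", {
  cfg <- test_config()
  a <- sweep_constant_energy(durations = c(1e-5, 3e-5), config = cfg)
  b <- sweep_constant_energy(durations = c(1e-5, 3e-5), config = cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("configuration errors are named and early", {
  expect_error(default_experiment_config(bogus_key = 1), "bogus_key")
  cfg <- test_config()
  cfg$mu_a_cm1 <- NULL
  expect_error(sweep_constant_energy(durations = 3e-5, config = cfg),
               "mu_a_cm1")
})

test_that("run_all writes the full report bundle", {
  out <- file.path(tempdir(), "oc-run-all")
  unlink(out, recursive = TRUE)
  cfg_file <- tempfile(fileext = ".yaml")
  writeLines("mu_a_cm1: 10.0", cfg_file)
  res <- suppressMessages(run_all(cfg_file, out_dir = out))
  expect_true(all(file.exists(file.path(out, c(
    "sweep_constant_energy.csv", "sweep_constant_power.csv",
    "sweep_absorption.csv", "ink_series.csv", "summary.json")))))
  s <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(s$tau_th_s, 4.92e-3, tolerance = 1e-2)
  expect_equal(s$regime_30us, "thermal")
  expect_gt(s$derivative_fit_r_squared, 0.99)
  expect_lt(s$constant_power_onset_spread, 0.05)
  expect_equal(s$ink_slope_cm1_per_pct, 15.1, tolerance = 0.02)
  expect_gte(s$merge_threshold_s, 0.5e-3)
  expect_lte(s$merge_threshold_s, 2e-3)
  unlink(cfg_file)
  unlink(out, recursive = TRUE)
})
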