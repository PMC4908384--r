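test_that("flat-top pulses have exact plateau, energy and onset", {
  w <- make_flat_top(100e-6, 0.15, rise_time = 2e-6, fall_time = 2e-6)
  m <- pulse_metrics(w)
  expect_equal(m$peak_power, 0.15)
  expect_equal(m$energy, 15e-6, tolerance = 1e-6)
  # onset (start of rise) sits at the configured pre-delay
  w2 <- make_flat_top(30e-6, 0.2, pre_delay = 1e-5)
  dt <- w2$t[2] - w2$t[1]
  expect_lt(abs(min(w2$t[w2$P > 0]) - 1e-5), 2 * dt)
})

test_that("flat-top energy targeting: 30 us at 0.2 W gives 6 uJ", {
  w <- make_flat_top(30e-6, 0.2)
  # trapezoid quadrature oracle on the sampled record
  expect_equal(sum(diff(w$t) * (head(w$P, -1) + tail(w$P, -1)) / 2),
               6e-6, tolerance = 1e-9)
})

test_that("invalid pulse parameters are rejected", {
  expect_error(make_flat_top(10e-6, 0), "positive")
  expect_error(make_flat_top(-1, 0.1), "positive")
  expect_error(make_flat_top(1e-6, 0.1, rise_time = 1e-6, fall_time = 1e-6),
               "exceed")
  expect_error(make_gaussian(1e-9, 1e-6, dt = 1e-9), "resolved")
})

test_that("gaussian pulses match the closed-form peak, energy and FWHM", {
  fwhm <- 5e-9
  g <- make_gaussian(fwhm, 6e-6, dt = 0.5e-9)
  m <- pulse_metrics(g)
  expect_equal(m$peak_power, 6e-6 / (fwhm * sqrt(pi / (4 * log(2)))),
               tolerance = 1e-3)
  expect_equal(m$energy, 6e-6, tolerance = 1e-3)
  expect_equal(m$fwhm, fwhm, tolerance = 0.5e-9)
  # linearity: doubling energy doubles every sample
  g2 <- make_gaussian(fwhm, 12e-6, dt = 0.5e-9)
  expect_equal(g2$P, 2 * g$P)
  # zero energy gives an all-zero waveform
  g0 <- make_gaussian(fwhm, 0, dt = 0.5e-9)
  expect_true(all(g0$P == 0))
})

test_that("power derivative is central in the interior, one-sided at ends", {
  t <- seq(0, 1e-5, by = 1e-7)
  k <- 3e4
  w <- pulse_waveform(t, k * t)
  d <- power_derivative(w)
  expect_equal(d$dPdt, rep(k, length(t)), tolerance = 1e-9)
  wc <- pulse_waveform(t, rep(0.5, length(t)))
  expect_true(all(power_derivative(wc)$dPdt == 0))
  # flat-top: max slope equals peak/rise, extrema at rise and fall
  ft <- make_flat_top(30e-6, 0.2, rise_time = 2e-6, fall_time = 2e-6)
  dft <- power_derivative(ft)
  expect_equal(dft$max_dPdt, 0.2 / 2e-6, tolerance = 1e-6)
  expect_equal(dft$min_dPdt, -0.2 / 2e-6, tolerance = 1e-6)
  # derivative of a completed pulse integrates to zero
  expect_lt(abs(sum(dft$dPdt) * (ft$t[2] - ft$t[1])), 1e-12)
  # exactly one contiguous positive and one negative excursion
  s <- sign(dft$dPdt[abs(dft$dPdt) > 1e-6 * dft$max_dPdt])
  expect_equal(sum(diff(s) != 0), 1)
  expect_error(power_derivative(pulse_waveform(t[1:2], c(0, 0))), "3 samples")
})

test_that("pulse metrics respect symmetry and the constant-slope law", {
  # symmetric pulse: max derivative equals minus the min derivative
  g <- make_gaussian(1e-6, 1e-6)
  m <- pulse_metrics(g)
  expect_equal(m$max_dPdt, -m$min_dPdt, tolerance = 1e-6)
  # fixed plateau power and rise time: same max slope for all durations
  slopes <- vapply(c(1e-5, 1e-4, 1e-3), function(d) {
    pulse_metrics(make_flat_top(d, 0.15))$max_dPdt
  }, numeric(1))
  expect_lt(diff(range(slopes)) / mean(slopes), 1e-6)
  # constant energy: max slope decreases monotonically with duration
  s_e <- vapply(c(5e-6, 2e-5, 1e-4), function(d) {
    pulse_metrics(make_flat_top(d, 6e-6 / d))$max_dPdt
  }, numeric(1))
  expect_true(all(diff(s_e) < 0))
  expect_warning(m0 <- pulse_metrics(pulse_waveform(seq(0, 1e-5, 1e-7),
                                                    numeric(101))),
                 "FWHM")
  expect_true(is.na(m0$fwhm))
})

test_that("energies of disjoint pulses add", {
  t <- seq(0, 2e-4, by = 1e-7)
  p1 <- ifelse(t > 1e-5 & t < 3e-5, 0.1, 0)
  p2 <- ifelse(t > 1e-4 & t < 1.5e-4, 0.2, 0)
  e <- function(p) pulse_metrics(pulse_waveform(t, p))$energy
  expect_equal(e(p1 + p2), e(p1) + e(p2), tolerance = 1e-9)
})

test_that("period/frequency conversion matches the audiogram argument", {
  expect_equal(period_to_frequency(80e-6), 12500)
  expect_equal(period_to_frequency(125e-6), 8000)
  expect_equal(period_to_frequency(1), 1)
  expect_error(period_to_frequency(0), "positive")
  expect_error(period_to_frequency(-1e-6), "positive")
})

test_that("waveform CSV round-trips and supports detector-limited ingestion", {
  w <- make_flat_top(30e-6, 0.2)
  f <- tempfile(fileext = ".csv")
  write_pulse_csv(w, f)
  w2 <- read_pulse_csv(f)
  expect_equal(w2$t, w$t)
  expect_equal(w2$P, w$P)
  # 25 ns detector rise barely distorts a microsecond-scale ramp
  w3 <- read_pulse_csv(f, detector_rise = 25e-9)
  expect_equal(pulse_metrics(w3)$energy, 6e-6, tolerance = 1e-3)
  unlink(f)
})
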