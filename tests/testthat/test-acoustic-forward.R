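test_that("heating source conserves absorbed energy and scales with mu_a", {
  src <- build_heating_source(6e-6, 52.5e-6, 10, axial_cutoff = 5e-3)
  expect_equal(sum(src$A_e * src$vol), 1 - exp(-10 * 100 * 5e-3),
               tolerance = 5e-3)
  expect_equal(sum(src$A_e * src$vol), 0.993, tolerance = 1e-3)
  expect_lte(sum(src$A_e * src$vol), 1)
  expect_true(all(src$A_e >= 0))
  # axial decay is monotone along the axis
  on_axis <- src$A_e[src$rho == min(src$rho)]
  z_ax <- src$z[src$rho == min(src$rho)]
  expect_true(all(diff(on_axis[order(z_ax)]) <= 0))
  # doubling mu_a doubles the surface deposition density
  src2 <- build_heating_source(6e-6, 52.5e-6, 20, axial_cutoff = 5e-3)
  expect_equal(max(src2$A_e) / max(src$A_e), 2, tolerance = 0.01)
  expect_error(build_heating_source(6e-6, 52.5e-6, 10, voxels_per_scale = 3),
               "resolution")
  expect_error(build_heating_source(0, 52.5e-6, 10), "positive")
})

test_that("initial pressure is the Grueneisen conversion", {
  expect_equal(initial_pressure(1e6, 0.11), 1.1e5)
  expect_equal(initial_pressure(0, 0.11), 0)
  expect_error(initial_pressure(-1, 0.11), "non-negative")
  # Grueneisen from water constants at room temperature is close to 0.11
  m <- medium_properties()
  expect_equal(m$grueneisen, 0.11, tolerance = 0.05)
})

test_that("solver matches the closed-form heated-sphere N-wave within 3%", {
  a <- 4e-4
  z0 <- 1e-2
  r_obs <- 5e-3
  src <- ball_source(a, z0)
  pulse <- make_gaussian(8e-8, 6e-6, dt = 3e-9)
  tr <- suppressWarnings(
    pressure_at_point(src, pulse, field_point(axial_offset = z0 + r_obs)))
  p0 <- medium_properties()$grueneisen * 6e-6 * 3 / (4 * pi * a^3)
  oracle <- sphere_oracle(tr$t, pulse, a, r_obs, p0)
  expect_lt(max(abs(tr$p - oracle)) / max(abs(oracle)), 0.03)
})

test_that("flat-top response is bipolar with silent plateau", {
  src <- build_heating_source(6e-6, 52.5e-6, 10)
  w <- make_flat_top(2e-3, 0.15)
  tr <- suppressWarnings(pressure_at_point(src, w))
  imax <- which.max(tr$p)
  imin <- which.min(tr$p)
  # opposite polarity, onset before offset
  expect_gt(tr$p[imax], 0)
  expect_lt(tr$p[imin], 0)
  expect_lt(tr$t[imax], tr$t[imin])
  # separation equals the pulse duration to within one pulse sample
  expect_equal(tr$t[imin] - tr$t[imax], 2e-3,
               tolerance = (w$t[2] - w$t[1]) / 2e-3)
  # no pressure during the constant-power plateau
  mid <- tr$t > tr$t[imax] + 3e-4 & tr$t < tr$t[imin] - 3e-4
  expect_lt(max(abs(tr$p[mid])), 0.01 * tr$peak_abs)
})

test_that("solver is linear in pulse energy and equivariant to delays", {
  src1 <- build_heating_source(6e-6, 52.5e-6, 10)
  src2 <- build_heating_source(12e-6, 52.5e-6, 10)
  w1 <- make_flat_top(3e-5, 0.2)
  w2 <- make_flat_top(3e-5, 0.4)   # same shape, twice the energy
  t1 <- suppressWarnings(pressure_at_point(src1, w1))
  t2 <- suppressWarnings(pressure_at_point(src2, w2))
  n <- min(length(t1$p), length(t2$p))
  expect_equal(t2$p[1:n], 2 * t1$p[1:n], tolerance = 1e-9)
  # shifting the pulse shifts the trace by the same amount
  dt <- w1$t[2] - w1$t[1]
  shift <- 200 * dt
  w3 <- make_flat_top(3e-5, 0.2, pre_delay = 5e-6 + shift)
  t3 <- suppressWarnings(pressure_at_point(src1, w3))
  expect_equal(t3$t[which.max(t3$p)] - t1$t[which.max(t1$p)], shift,
               tolerance = 2 * dt / shift)
})

test_that("far-field peak amplitude decays as 1/distance", {
  src <- build_heating_source(6e-6, 52.5e-6, 10)
  w <- make_flat_top(3e-5, 0.2)
  pk <- vapply(c(0.02, 0.06, 0.2), function(d) {
    pressure_at_point(src, w, field_point(axial_offset = d))$peak_abs * d
  }, numeric(1))
  expect_lt(diff(range(pk)) / mean(pk), 0.05)
})

test_that("a field point inside the source is flagged as near field", {
  src <- build_heating_source(6e-6, 52.5e-6, 10)
  w <- make_flat_top(3e-5, 0.2)
  expect_warning(tr <- pressure_at_point(src, w, field_point(1e-4)),
                 "near-field")
  expect_true(tr$meta$near_field)
  far <- pressure_at_point(src, w, field_point(2e-2))
  expect_false(far$meta$near_field)
  # lateral placement outside the beam is not near field
  side <- pressure_at_point(
    src, w, field_point(axial_offset = 1e-3, lateral_offset = 1e-4))
  expect_false(side$meta$near_field)
})

test_that("measurement chain preserves the passband and event timing", {
  fs <- 2.04e6
  t <- seq(0, 5e-3, by = 1 / fs)
  tone <- pressure_trace(t, sin(2 * pi * 5e3 * t))
  out <- apply_measurement_chain(tone)
  inner <- out$t > 1e-3 & out$t < 4e-3   # avoid edge transients
  expect_equal(max(abs(out$p[inner])), 1, tolerance = 0.01)
  # a click keeps its timing through the zero-phase filter
  click <- pressure_trace(t, exp(-(t - 2.5e-3)^2 / (2 * (2e-6)^2)))
  outc <- apply_measurement_chain(click)
  expect_lt(outc$peak_abs, 1)
  expect_lt(abs(outc$t[which.max(outc$p)] - 2.5e-3), 1 / 1.02e5)
  expect_error(apply_measurement_chain(tone, bandwidth = 2e6), "Nyquist")
  expect_error(apply_measurement_chain(tone, sampling_rate = 1e7),
               "not exceed")
})

test_that("decimation preserves sub-sample transient content", {
  # a zero-net-area compression/rarefaction pair far shorter than one
  # intermediate filter sample must still produce the response predicted by
  # direct frequency-domain filtering
  fs <- 1e9
  t <- seq(0, 3e-6, by = 1 / fs)
  w <- 3e-8
  p <- exp(-(t - 1e-6)^2 / (2 * w^2)) - exp(-(t - 1e-6 - 1e-7)^2 / (2 * w^2))
  tr <- pressure_trace(t, p)
  out <- apply_measurement_chain(tr, pad = c(2e-4, 2e-4))
  # frequency-domain oracle: zero-phase squared 4th-order Butterworth
  nbig <- 2^17
  x <- c(p, numeric(nbig - length(p)))
  f <- (0:(nbig - 1)) / nbig * fs
  f <- pmin(f, fs - f)
  y <- Re(stats::fft(stats::fft(x) / (1 + (f / 1e5)^8), inverse = TRUE)) / nbig
  # compare passband content (the 102 kHz resampling undersamples the
  # filtered oscillation, so allow for the sampled-peak capture loss)
  expect_gt(out$peak_abs, 0.3 * max(abs(y)))
  expect_lt(out$peak_abs, 1.1 * max(abs(y)))
})

test_that("SPL conversion uses the 1 uPa underwater reference", {
  expect_equal(spl_re_1uPa(1e-6), 0)
  expect_equal(spl_re_1uPa(100), 160)
  expect_equal(spl_re_1uPa(3.16), 130, tolerance = 1e-3)
  expect_error(spl_re_1uPa(0), "positive")
})

test_that("pressure trace CSV round-trips", {
  tr <- pressure_trace(seq(0, 1e-3, 1e-6), sin(seq(0, 1e-3, 1e-6) * 2e4))
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  tr2 <- read_trace_csv(f)
  expect_equal(tr2$p, tr$p)
  expect_equal(tr2$peak_abs, tr$peak_abs)
  unlink(f)
})
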