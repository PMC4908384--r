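#' Voxelized energy-deposition source at a fiber tip
#'
#' Discretizes the illuminated volume in front of an optical fiber as
#' azimuthally symmetric rings (cylindrical coordinates): a top-hat radial
#' fluence profile inside the core radius and exponential Beer-Lambert decay
#' along the axis. `A_e` is the deposited optical energy per unit volume per
#' unit pulse energy (1/m^3), so `A_e * E` is the energy-deposition density
#' in J/m^3 and the volume integral of `A_e` equals the absorbed fraction
#' `1 - exp(-mu_a * L)`.
#'
#' @param pulse_energy pulse energy in joules (stored in the grid metadata;
#'   `A_e` itself is normalized per unit energy).
#' @param fiber_radius fiber core radius, m (default 52.5 um, a 105 um core).
#' @param mu_a absorption coefficient, 1/cm.
#' @param axial_cutoff axial extent of the grid, m; default
#'   `min(5/mu_a, 5 mm)` (over 99% of the absorbable energy).
#' @param voxels_per_scale number of voxels across the smallest source
#'   dimension `min(1/mu_a, fiber_radius)`, radially and axially; at least 5.
#'
#' @return A `source_grid`: list with ring centres `rho`, `z` (m), `A_e`
#'   (1/m^3), ring volumes `vol` (m^3), and the geometry metadata.
#' @export
build_heating_source <- function(pulse_energy, fiber_radius = 52.5e-6,
                                 mu_a = 1.34, axial_cutoff = NULL,
                                 voxels_per_scale = 10) {
  if (pulse_energy <= 0 || fiber_radius <= 0 || mu_a <= 0) {
    stop_invalid("pulse_energy, fiber_radius and mu_a must be positive")
  }
  mu_m <- mu_a * 100                      # 1/m
  scale <- min(1 / mu_m, fiber_radius)
  axial_cutoff <- axial_cutoff %||% min(5 / mu_m, 5e-3)
  if (axial_cutoff <= 0) stop_invalid("'axial_cutoff' must be positive")
  if (voxels_per_scale < 5) {
    stop_invalid("resolution too coarse: need >= 5 voxels per source scale")
  }
  h <- scale / voxels_per_scale           # target voxel edge, both directions
  nr <- max(voxels_per_scale, ceiling(fiber_radius / h))
  nz <- ceiling(axial_cutoff / h)
  dr <- fiber_radius / nr
  dz <- axial_cutoff / nz
  rho <- (seq_len(nr) - 0.5) * dr
  z <- (seq_len(nz) - 0.5) * dz
  # ring volume: pi*(r_out^2 - r_in^2)*dz, exact for the annulus
  ring_area <- pi * ((rho + dr / 2)^2 - (rho - dr / 2)^2)
  # axial factor: exact shell-averaged deposition so conservation holds to
  # quadrature accuracy: integral of mu*exp(-mu*z) over the cell / dz
  ax <- (exp(-mu_m * (z - dz / 2)) - exp(-mu_m * (z + dz / 2))) / dz
  grid <- expand.grid(iz = seq_len(nz), ir = seq_len(nr))
  A_e <- ax[grid$iz] / (pi * fiber_radius^2)
  vol <- ring_area[grid$ir] * dz
  structure(
    list(rho = rho[grid$ir], z = z[grid$iz], A_e = A_e, vol = vol,
         fiber_radius = fiber_radius, mu_a = mu_a,
         axial_extent = axial_cutoff, pulse_energy = pulse_energy,
         voxel_size = c(dr = dr, dz = dz)),
    class = "source_grid"
  )
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf(
    "<source_grid> %d rings, r = %.3g m, mu_a = %.3g /cm, L = %.3g m\n",
    length(x$A_e), x$fiber_radius, x$mu_a, x$axial_extent))
  cat(sprintf("  absorbed fraction %.4f (expected %.4f)\n",
              sum(x$A_e * x$vol), 1 - exp(-x$mu_a * 100 * x$axial_extent)))
  invisible(x)
}

#' A field point relative to the fiber tip
#'
#' The fiber tip is at the origin with the beam propagating along +z.
#' `axial_offset` is the on-axis distance beyond the tip (into the absorbing
#' medium), `lateral_offset` the perpendicular distance from the beam axis.
#'
#' @param axial_offset m.
#' @param lateral_offset m.
#' @export
field_point <- function(axial_offset = 1e-4, lateral_offset = 0) {
  d <- sqrt(axial_offset^2 + lateral_offset^2)
  if (!is.finite(d) || d <= 0) {
    stop_invalid("field point must be at a positive distance from the tip")
  }
  structure(list(axial_offset = axial_offset,
                 lateral_offset = lateral_offset, distance = d),
            class = "field_point")
}

#' Pressure trace container
#'
#' @param t time, s.
#' @param p pressure, Pa.
#' @param meta optional list of provenance fields.
#' @return A `pressure_trace` with peak summaries `peak_positive`,
#'   `peak_negative` (signed) and `peak_abs`.
#' @export
pressure_trace <- function(t, p, meta = list()) {
  stopifnot(length(t) == length(p))
  structure(list(t = as.numeric(t), p = as.numeric(p),
                 peak_positive = max(p), peak_negative = min(p),
                 peak_abs = max(abs(p)), meta = meta),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf(
    "<pressure_trace> %d samples, dt = %.3g s, peaks +%.3g / %.3g Pa\n",
    length(x$t), grid_step(x$t), x$peak_positive, x$peak_negative))
  if (isTRUE(x$meta$near_field)) {
    cat("  note: field point lies inside the source volume (near field)\n")
  }
  invisible(x)
}

#' Initial optoacoustic pressure
#'
#' Under stress confinement the deposited energy density converts into an
#' initial pressure p0 = Grueneisen * A_e, with A_e the volumetric optical
#' energy deposition in J/m^3.
#'
#' @param A_e_density energy-deposition density, J/m^3.
#' @param grueneisen dimensionless Grueneisen coefficient.
#' @return p0 in Pa.
#' @export
initial_pressure <- function(A_e_density, grueneisen = 0.11) {
  if (any(A_e_density < 0) || any(grueneisen < 0)) {
    stop_invalid("inputs must be non-negative")
  }
  grueneisen * A_e_density
}

#' Optoacoustic pressure waveform at a field point
#'
#' Evaluates the retarded-time volume integral of the linear optoacoustic
#' wave equation for a heat source separable into a fixed spatial deposition
#' profile and the laser power time course:
#'
#'   p(x, t) = Gamma / (4 pi c^2) * sum_v A_e(v) vol(v) P'(t - R_v / c) / R_v
#'
#' with P' the numerical power derivative (linearly interpolated at retarded
#' times). Because the pressure is driven by P', a flat-top pulse produces a
#' bipolar response: a compression locked to the pulse onset and a
#' rarefaction locked to the offset, separated by exactly the pulse
#' duration, with no pressure generated during the constant-power plateau.
#'
#' The time grid is refined internally so that `c * dt` is smaller than half
#' a voxel, and voxel contributions are accumulated into a retarded-delay
#' histogram (linear split between neighbouring bins) that is convolved with
#' P' by FFT; this is algebraically the same sum evaluated efficiently.
#'
#' A field point inside the source cylinder is allowed (the integral is
#' finite); the returned trace then carries `meta$near_field = TRUE`.
#'
#' @param source a [build_heating_source()] grid (its `pulse_energy` scales
#'   the result).
#' @param pulse a [pulse_waveform()]; its grid must resolve its own rise
#'   time with at least 10 samples.
#' @param field a [field_point()].
#' @param medium a [medium_properties()].
#'
#' @return A [pressure_trace()] starting at the pulse record start, extended
#'   by the maximum source transit delay.
#' @export
pressure_at_point <- function(source, pulse, field = field_point(),
                              medium = medium_properties()) {
  stopifnot(inherits(source, "source_grid"), inherits(pulse, "pulse_waveform"),
            inherits(field, "field_point"))
  d <- power_derivative(pulse)
  # resolution guard: the rise must be sampled; estimate rise as the time P'
  # stays above half its max around the onset
  dt0 <- grid_step(pulse$t)
  rise_samples <- sum(d$dPdt > d$max_dPdt / 2)
  if (rise_samples < 10) {
    stop_invalid("pulse grid does not resolve its rise time (need >= 10 samples)")
  }
  cs <- medium$c
  vox <- min(source$voxel_size)
  dt <- min(dt0, vox / (2 * cs))
  # distances from each ring to the field point; lateral offset breaks the
  # ring symmetry, so rings are subdivided azimuthally when it is non-zero
  if (field$lateral_offset == 0) {
    R <- sqrt(source$rho^2 + (source$z - field$axial_offset)^2)
    w <- source$A_e * source$vol / R
  } else {
    nphi <- 36L
    phi <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
    dx2 <- outer(source$rho, phi, function(r, ph) {
      (r * cos(ph) - field$lateral_offset)^2 + (r * sin(ph))^2
    })
    R <- sqrt(dx2 + (source$z - field$axial_offset)^2)
    w <- as.vector((source$A_e * source$vol / nphi) / R)
    R <- as.vector(R)
  }
  delay <- R / cs
  # retarded-delay histogram on the refined grid, linear bin split
  nb <- floor(max(delay) / dt) + 2L
  k <- floor(delay / dt)
  frac <- delay / dt - k
  h <- numeric(nb)
  acc1 <- tapply(w * (1 - frac), k, sum)
  acc2 <- tapply(w * frac, k + 1L, sum)
  h[as.integer(names(acc1)) + 1L] <- acc1
  i2 <- as.integer(names(acc2)) + 1L
  h[i2] <- h[i2] + acc2
  # P' interpolated onto the refined grid, scaled to absolute power
  tt <- seq(pulse$t[1], pulse$t[length(pulse$t)] + max(delay) + 10 * dt,
            by = dt)
  dP <- stats::approx(d$t, d$dPdt, xout = tt, yleft = 0, yright = 0)$y
  # A_e is normalized per unit pulse energy and P' carries absolute watts,
  # so no explicit energy factor appears here
  K <- medium$grueneisen / (4 * pi * cs^2)
  p <- fft_convolve(dP, h) * K
  p <- p[seq_along(tt)]
  near <- field$lateral_offset < source$fiber_radius &&
    field$axial_offset > 0 && field$axial_offset < source$axial_extent
  if (near) {
    warning("field point lies inside the source volume; near-field result",
            call. = FALSE)
  }
  pressure_trace(tt, p, meta = list(near_field = near,
                                    distance = field$distance,
                                    dt = dt, mu_a = source$mu_a))
}

# linear convolution via FFT, returning length(x) + length(k) - 1 samples
fft_convolve <- function(x, k) {
  n <- length(x) + length(k) - 1L
  nfft <- stats::nextn(n, 2)
  Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                  stats::fft(c(k, numeric(nfft - length(k)))),
                inverse = TRUE))[seq_len(n)] / nfft
}

#' Apply the hydrophone measurement chain
#'
#' Emulates the recording electronics: a low-pass amplifier bandwidth
#' (default 100 kHz, 4th-order Butterworth applied forward-backward so
#' timing is preserved) followed by resampling at the acquisition rate
#' (default 102 kHz). The filter runs at an intermediate rate of at least
#' 16x the bandwidth so the Butterworth design is well conditioned even for
#' nanosecond-resolution input.
#'
#' @param trace a [pressure_trace()].
#' @param bandwidth low-pass corner frequency, Hz.
#' @param sampling_rate output sampling rate, Hz; must not exceed the input
#'   rate.
#' @param pad zero-pressure padding `c(before, after)` in seconds, added at
#'   the filter's internal rate so short high-resolution solver records can
#'   be embedded in a realistically long acquisition window at no memory
#'   cost.
#'
#' @return A [pressure_trace()] on the new grid.
#' @export
apply_measurement_chain <- function(trace, bandwidth = 1e5,
                                    sampling_rate = 1.02e5, pad = c(0, 0)) {
  stopifnot(inherits(trace, "pressure_trace"))
  fs_in <- 1 / grid_step(trace$t)
  if (sampling_rate > fs_in) {
    stop_invalid("'sampling_rate' must not exceed the input rate")
  }
  if (bandwidth > fs_in / 2) {
    stop_invalid("'bandwidth' exceeds the Nyquist frequency of the trace")
  }
  # intermediate rate: high enough for fidelity, low enough for a
  # well-conditioned filter design
  fs_mid <- min(fs_in, max(16 * bandwidth, 4 * sampling_rate))
  t_mid <- seq(trace$t[1] - pad[1], trace$t[length(trace$t)] + pad[2],
               by = 1 / fs_mid)
  if (fs_in > 1.5 * fs_mid) {
    # decimation to the filter rate projects each input sample onto the two
    # bracketing coarse nodes (adjoint of linear interpolation). This
    # preserves both the area and the first moment of the waveform, so
    # transients much shorter than one intermediate sample - including
    # zero-net-area compression/rarefaction pairs - still drive the filter
    # with the correct low-frequency content.
    pos <- (trace$t - t_mid[1]) * fs_mid
    k <- floor(pos)
    frac <- pos - k
    amp <- trace$p * (fs_mid / fs_in)
    x <- numeric(length(t_mid))
    for (part in list(list(k + 1L, 1 - frac), list(k + 2L, frac))) {
      ok <- part[[1]] >= 1L & part[[1]] <= length(t_mid)
      s <- rowsum(amp[ok] * part[[2]][ok], part[[1]][ok])
      x[as.integer(rownames(s))] <- x[as.integer(rownames(s))] + s
    }
  } else {
    x <- stats::approx(trace$t, trace$p, xout = t_mid,
                       yleft = 0, yright = 0)$y
  }
  bf <- signal::butter(4, bandwidth / (fs_mid / 2), type = "low")
  x <- signal::filtfilt(bf, x)
  t_out <- seq(t_mid[1], t_mid[length(t_mid)], by = 1 / sampling_rate)
  p_out <- stats::approx(t_mid, x, xout = t_out)$y
  pressure_trace(t_out, p_out,
                 meta = c(trace$meta,
                          list(bandwidth = bandwidth,
                               sampling_rate = sampling_rate)))
}

#' Sound pressure level re 1 uPa
#'
#' The underwater-acoustics decibel scale: 20 log10(p / 1e-6 Pa).
#'
#' @param peak_pressure pressure in Pa, positive.
#' @return SPL in dB re 1 uPa.
#' @export
spl_re_1uPa <- function(peak_pressure) {
  if (any(!is.finite(peak_pressure)) || any(peak_pressure <= 0)) {
    stop_invalid("'peak_pressure' must be positive")
  }
  20 * log10(peak_pressure / 1e-6)
}

#' Read / write pressure traces as two-column CSV
#'
#' Format: header `time_s,pressure_Pa`, one row per sample.
#' @param path file path.
#' @param trace a [pressure_trace()] (writer only).
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path, header = TRUE)
  if (!all(c("time_s", "pressure_Pa") %in% names(d))) {
    stop_invalid("expected columns 'time_s' and 'pressure_Pa'")
  }
  pressure_trace(d$time_s, d$pressure_Pa)
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "pressure_trace"))
  utils::write.csv(data.frame(time_s = trace$t, pressure_Pa = trace$p), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
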