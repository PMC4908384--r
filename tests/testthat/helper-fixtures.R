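# shared fixtures: built in code, deliberately small so the default test run
# stays fast

# reduced-resolution experiment config for sweep-level tests
test_config <- function(...) {
  default_experiment_config(...)
}

# uniformly heated ball source for the closed-form N-wave cross-check:
# rings covering a sphere of radius a centred on the axis at z = z0
ball_source <- function(a, z0, nvox = 32, energy = 6e-6) {
  h <- a / nvox
  rho <- seq(h / 2, a, by = h)
  z <- seq(-a + h / 2, a, by = h)
  gr <- expand.grid(rho = rho, z = z)
  gr <- gr[gr$rho^2 + gr$z^2 <= a^2, ]
  vol <- 2 * pi * gr$rho * h * h
  structure(
    list(rho = gr$rho, z = gr$z + z0,
         A_e = rep(1 / sum(vol), nrow(gr)),  # uniform, discretely normalized
         vol = vol, fiber_radius = a, mu_a = 1,
         axial_extent = z0 + a, pulse_energy = energy,
         voxel_size = c(dr = h, dz = h)),
    class = "source_grid")
}

# closed-form pressure from a uniformly heated sphere (radius a, initial
# pressure p0 for delta deposition) at exterior distance r_obs, convolved
# with the normalized pulse power; independent of the volume-sum solver
sphere_oracle <- function(t, pulse, a, r_obs, p0, c_sound = 1484) {
  dt <- t[2] - t[1]
  nw <- ifelse(abs(r_obs - c_sound * t) <= a,
               p0 * (r_obs - c_sound * t) / (2 * r_obs), 0)
  pn <- stats::approx(pulse$t, pulse$P / pulse_metrics(pulse)$energy,
                      xout = t, yleft = 0, yright = 0)$y
  stats::convolve(nw, rev(pn), type = "open")[seq_along(t)] * dt
}
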