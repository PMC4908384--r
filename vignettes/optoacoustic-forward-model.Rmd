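---
title: "The optoacoustic forward model behind optocochlea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The optoacoustic forward model behind optocochlea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optocochlea)
```

## The physical problem

Pulsed laser light delivered into the fluid of the inner ear can evoke
auditory responses. The candidate mechanism modelled here is the
optoacoustic (photoacoustic) effect: absorbed light transiently heats a
small volume of fluid in front of the optical fiber, thermal expansion
launches a pressure wave, and that wave deflects the basilar membrane like
ordinary sound. `optocochlea` implements the full forward chain for the
water-tank analogue of this experiment — laser pulse shape, optical
absorption, acoustic wave generation and propagation to a hydrophone-like
field point, the recording electronics, and a surrogate for the compound
action potential (CAP) of the auditory nerve — so that the characteristic
signatures of the mechanism can be simulated and tested quantitatively.

## Model and assumptions

### Heat deposition

The fiber (core radius $r$ = 52.5 µm by default) emits a top-hat beam into
an absorbing medium with absorption coefficient $\mu_a$. Beam divergence is
neglected (NA 0.22 over the ~0.1–5 mm scales involved adds less than half a
core radius), so the deposited optical energy per unit volume and unit
pulse energy is

$$A_e(\rho, z) = \frac{\mu_a e^{-\mu_a z}}{\pi r^2},
  \qquad \rho \le r,$$

which integrates to the absorbed fraction $1 - e^{-\mu_a L}$ over the grid
of axial extent $L$. `build_heating_source()` discretizes this on
azimuthally symmetric rings and uses the exact per-cell shell average of
the exponential so the conservation identity holds to quadrature accuracy
(tested at 0.5%). The heating function separates as
$H(\mathbf{x}, t) = A_e(\mathbf{x})\,P(t)$ with $P$ the optical power.

### Confinement scales

Two algebraic time scales classify a pulse of duration $\tau$
(`classify_regime()`): the thermal confinement limit
$\tau_{th} = \delta^2/4\kappa$ and the stress confinement limit
$\tau_p = \delta/c$, where $\delta = \min(1/\mu_a, r)$ is the smallest
dimension of the heated volume, $\kappa$ the thermal diffusivity and $c$
the speed of sound. For water and the 105 µm fiber these evaluate to
4.9 ms and 35 ns. Boundaries are inclusive toward the tighter regime. The
dimensionless product $\mu_a \delta$ classifies the source geometry
(extended cylinder below 0.1, thin disk above 10, transition between);
the 0.1/10 cut-offs are package choices — the underlying asymptotic
statements are only about products far below or above one.

### Acoustic forward model

In the linear, inviscid, thermally confined regime the pressure at a field
point $\mathbf{x}$ is the retarded-time volume integral

$$p(\mathbf{x}, t) = \frac{\Gamma}{4\pi c^2}
  \int \frac{A_e(\mathbf{x}')\,P'(t - |\mathbf{x}-\mathbf{x}'|/c)}
            {|\mathbf{x}-\mathbf{x}'|}\, dV',$$

with $\Gamma = \beta c^2 / C_p$ the Grüneisen coefficient (≈ 0.11 for
water at room temperature; computed from $\beta$, $c$, $C_p$ rather than
set directly, and cross-checked within 5%). Because the source term is the
*time derivative* of the laser power, a flat-top pulse produces a
compression locked to the onset ramp and a rarefaction locked to the
offset ramp, separated by exactly the pulse duration, and nothing during
the constant-power plateau. These are the signatures the package's tests
pin down: opposite polarity, interval equal to duration within one sample,
plateau pressure below 1% of the peak, amplitude linear in pulse energy and
in the maximum of $P'$.

`pressure_at_point()` evaluates the integral by binning voxel
contributions $A_e\,\mathrm{vol}/R$ into a retarded-delay histogram
(linear split between neighbouring bins) and convolving it with $P'$ by
FFT — algebraically the same sum, evaluated in
$O(n_{voxels} + n_t \log n_t)$. The time grid is refined so that $c\,dt$
is below half a voxel. The solver is validated against an independent
closed-form oracle: the N-wave of a uniformly heated sphere (delta-pulse
solution $p = p_0 (r - ct)/2r$ on $|r - ct| \le a$, convolved with the
normalized pulse power), matched within 3% $L_\infty$ at 32 voxels per
sphere radius.

A field point inside the illuminated cylinder is permitted — the integral
is finite — and flagged as near-field. The default geometry places the
field point on the beam axis 0.1 mm beyond the tip. The experimental
description of the hydrophone ("next to the fiber, 0.1 mm") leaves
axial/lateral ambiguous; on-axis is the documented default and a
`lateral_offset` is available (rings are subdivided azimuthally when the
symmetry is broken).

### Measurement chain

`apply_measurement_chain()` models the recording electronics: a 100 kHz
low-pass (4th-order Butterworth, applied forward-backward so event timing
is preserved) followed by resampling at 102 kHz, the acquisition rate of
the modelled experiment. Two numerical points matter:

* Decimation from the solver's nanosecond grid to the filter's internal
  rate (16× the bandwidth) projects samples onto the two bracketing coarse
  nodes — the adjoint of linear interpolation. This preserves the area
  *and the first moment* of the waveform, so a zero-net-area
  compression/rarefaction pair much shorter than one coarse sample still
  drives the filter correctly (verified against direct frequency-domain
  filtering of the fine trace; point sampling or plain bin averaging both
  lose such transients entirely).
* The final 102 kHz stage is deliberate point sampling, as an ADC does.
  A 100 kHz-bandwidth oscillation sampled at 102 kHz is undersampled, so
  the sampled peak underestimates the filtered peak — a faithful
  reproduction of the acquisition limit of the modelled setup.

### CAP surrogate

`cap_response()` maps a pressure trace to a CAP-like response: band-pass
5 Hz–5 kHz (6th-order Butterworth as cascaded 3rd-order high- and low-pass
halves, which stays numerically well conditioned at a 5 Hz corner), then
full-wave rectification (the nerve responds to either polarity of
basilar-membrane deflection), then convolution with a unit-area alpha
kernel $k(t) = (t/\tau^2) e^{-t/\tau}$ representing the prolonged
integration of the compound nerve response. The kernel time constant is
the one deliberately *tuned* parameter of the package: $\tau$ = 0.8 ms is
chosen so that the smallest flat-top duration with two separable response
peaks (`merge_threshold()`, computed by bisection) falls at ≈ 1.0 ms,
matching the observation that separate onset/offset CAPs appear only for
pulses longer than about 1 ms while hydrophone traces resolve both events
at all durations. It is a calibration, not a fit: no waveform data
constrain its shape. Response amplitudes are reported in arbitrary units;
no absolute µV prediction is attempted.

## Synthetic data

Every stage can be exercised without measured data
(`generate_photodiode_trace()`, `generate_hydrophone_recording()`,
`generate_ink_series()`). The generators are pure functions of their
parameters and one integer seed (replicates drawn sequentially from a
single seeded stream; the caller's RNG state is restored). They emulate:

* photodiode records — first-order low-pass with 25 ns detector rise time
  plus additive Gaussian noise (default σ = 0.5% of peak);
* hydrophone records — the mean of $N$ independent noisy replicates
  (default $N$ = 10\,000, single-shot σ = 10% of the reference peak so
  averaging matters); residual noise follows $\sigma/\sqrt{N}$, tested at
  20% tolerance over 100 seeds;
* ink dilution series — $\mu_a$ linear in concentration (slope
  15.1 cm⁻¹/%, chosen so that 5% ink reaches ≈ 77 cm⁻¹ from the water
  intercept of 1.34 cm⁻¹ at 1300 nm), Beer–Lambert transmission over a
  1 cm cuvette (configurable; the real cuvette size is not documented)
  with multiplicative noise, and an "outside measurement range" flag below
  a transmission of 10⁻⁴.

They do **not** emulate electrical artifacts, mains hum, physiological
noise spectra, hydrophone ringing or spatial averaging over a finite
sensor aperture. Passing tests therefore demonstrate the internal
consistency of the model chain, not agreement with raw laboratory traces.

The measurement noise floor of the modelled experiment is not documented;
the defaults above are stated assumptions. One consequence is documented
honestly: with the default noise floor, the model still classifies a
400 µs / 6 µJ pulse as detectable (3× residual noise), whereas the
modelled experiment reported no detectable signals at and beyond 400 µs.
The detectability mechanics are implemented and tested; this particular
observation is not reproduced by the linear model plus assumed noise.

## The parameter studies

`sweep_constant_energy()`, `sweep_constant_power()` and
`sweep_absorption()` script the three water-tank parameter studies
(constant 6 µJ over 5 ns–200 µs; constant 150 mW over 10 µs–10 ms;
$\mu_a$ from 1.34 to 124 cm⁻¹), each row running the full
pulse → source → solver → measurement chain → CAP pipeline.
`run_all()` executes everything from a configuration list or YAML file and
writes CSVs plus a JSON summary; reruns are bit-identical.

Durations below 10 µs use a Gaussian pulse (the nanosecond OPO regime),
longer ones a flat-top with 1 µs linear ramps. The ramp time of the
long-pulse laser is not documented anywhere; 1 µs is the package default
and is exposed in the configuration — peak *pressure* values scale with
it, while the structural properties (polarity, intervals, constancy at
fixed peak power) do not.

The absorption sweep reports the location of its amplitude maximum and the
corresponding $\mu_a \delta$ product as a *diagnostic* only. The measured
reversal points (57.5 cm⁻¹ for water, 8.89 cm⁻¹ for ink, products 0.3 and
0.05) involve source-geometry physics that the linear point-receiver model
does not fully capture; with default settings the simulated raw-amplitude
curve peaks near 77 cm⁻¹ (product ≈ 0.4) — the same order, not the same
point. Asserting those numbers would overstate the model.

## Numerical choices

* Voxelization: ≥ 10 voxels across $\min(1/\mu_a, r)$ radially and
  axially; axial cutoff $\min(5/\mu_a, 5\,\mathrm{mm})$; below 5 voxels
  per scale the constructor refuses.
* Pulse grids: flat-top dt = duration/1000, floored at 1 ns and capped at
  a tenth of the shortest ramp; Gaussian dt = FWHM/50. The solver requires
  at least 10 samples across the rise and refines internally so
  $c\,dt < \mathrm{voxel}/2$.
* Derivatives: mean of forward and backward difference in the interior,
  one-sided at the endpoints (so the extrema are grid-stable).
* FWHM measurement: linear interpolation between the bracketing samples of
  the half-power crossings.
* Spectrum interpolation: linear in $\log \mu_a$ versus wavelength (water
  absorption spans decades; log-linear interpolation cannot go negative);
  no extrapolation outside 845–2100 nm. The bundled table is hand-entered
  from the standard water-absorption literature with the two anchors
  1.34 cm⁻¹ @ 1300 nm and 0.039 cm⁻¹ @ 845 nm exact.
* Ink calibration: OLS on non-extrapolated points only; flagged points
  receive predicted values; $R^2 = 1 - SS_{res}/SS_{tot}$ on fitted
  points.
* Acoustic attenuation in water is neglected (well below 1% under
  200 kHz over the millimetre distances involved). Tank reflections and
  cochlear resonances are out of scope.

## Problem sizes

The shipped test-suite and the analysis scripts run everything at the
scales that the physics requires but no larger: the default source grid is
≈ 9\,500 rings (10 radial × ~950 axial voxels at $\mu_a$ = 10 cm⁻¹),
solver records range from 10³ to 6×10⁶ samples depending on pulse
duration, Monte-Carlo properties use 100–300 seeds, and the slope-recovery
property uses 200 synthetic series. The complete suite runs in well under
a minute on a single core.

## Known limitations

* The model is linear and single-pulse: no cavitation, no nonlinear
  acoustics, no inter-pulse thermal build-up (repetition rate is
  irrelevant under these assumptions).
* Absolute CAP amplitudes, the in vivo CAP maximum at 80 µs (which needs
  the species audiogram — the package only provides the period-to-frequency
  helper that motivates it), and the exact measured reversal points are
  outside scope; they are replaced by diagnostics and structural
  properties.
* Peak SPL after the simulated 100 kHz / 102 kHz measurement chain is
  substantially lower than the raw field-point peak (≈ 108 vs ≈ 132 dB re
  1 µPa for the 6 µJ / 30 µs reference): the chain removes most of the
  energy of the microsecond onset transient, and the ADC stage
  undersamples what remains. A physical hydrophone with its own ringing
  and aperture averaging reports larger sampled peaks than a point
  receiver; reproducing that would require a transducer model that the
  available information does not constrain.
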