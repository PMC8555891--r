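---
title: "Thermoelastic stress waves from pulsed microwave exposure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermoelastic stress waves from pulsed microwave exposure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hpmwave)
```

## The problem

A single, very intense microwave pulse deposits energy in the head over
microseconds. The temperature rise is minute — on the order of a
millidegree — but it arrives faster than the tissue can mechanically
relax, so the heated region is *inertially confined* and the thermal
expansion launches pressure waves. Reflected and converging inside the
quasi-spherical cranium, these waves can focus into tensile (negative)
pressures far from the heated surface. Two well-separated physical
consequences follow:

* the **microwave-auditory (Frey) effect** — the cochlea detects the
  ringing of the intracranial cavity, at kilohertz frequencies set by the
  head size and the bulk wave speed of brain tissue; and
* at extreme incident power densities, tensile pressures that approach
  **cavitation** and blunt-impact injury bands.

`hpmwave` implements this two-stage analysis at desk scale: an FDTD
Maxwell solver for dosimetry on a voxel phantom, an adiabatic linear
heating model, and thermoelastic pressure-wave solvers with spectral and
injury-metric post-processing.

## Phantoms and tissue constants

The anatomical input is a synthetic layered ellipsoid
(`build_layered_head()`): concentric shells labelled outside-in skin (3
mm), skull (7 mm), CSF (3 mm), gray matter (6 mm), white matter interior,
plus a CSF-filled ventricular inclusion. We define `head_length` as the
anterior-posterior extent of the *cranium* (skull outer surface), 0.17 m
by default, which leaves a 0.15 m brain compartment; the skin lies
outside this length. Axis convention: x = left-right, y =
posterior-anterior, z = inferior-superior; "frontal" exposure propagates
along +y, "side" along +x, and the electric field is vertically (z)
polarized.

No measured property tables ship with a segmented model here, so every
constant is centralized in `tissue_property_table()`:

* dielectrics are Gabriel-style literature-typical values anchored at
  0.4/1/2/3 GHz and linearly interpolated (a single-frequency lookup —
  each exposure is a single carrier, so no dispersive model is fitted);
* brain acoustics are water-like: bulk wave speed 1450 m/s, volumetric
  thermal expansion `beta = 3 alpha = 3.6e-4` per degree C (water at body
  temperature); cortical bone has `alpha = 0.27e-4` per degree C but is
  mechanically inert in the wave stage;
* brain heat capacity defaults to 3600 J/(kg K);
* the bulk modulus is derived, `K = rho c^2`, so the pair is consistent
  by construction.

Probes sit at 25%, 50% and 75% of the brain's AP axis (occipital,
periventricular, frontal); the source model gives no coordinates for its
trace locations, so these are the package's own choice.

## EM dosimetry

`run_fdtd()` solves Maxwell's equations on the Yee grid with material
coefficients edge-averaged over the four adjacent cells. Two choices
deserve comment:

* **Plane-wave injection** uses the *scattered-field formulation*: the
  analytic incident wave enters as a volumetric source term wherever the
  material differs from vacuum. Compared with a total-field/scattered-
  field box this is exact for a plane wave (an empty grid reproduces
  `E0/sqrt(2)` RMS to machine precision) and has no face-leakage
  artifacts; the cost — evaluating the incident field in body voxels — is
  negligible at desk scale.
* **Absorbing boundaries** are a 10-cell convolutional PML with
  polynomial grading of order 3 and `sigma_max = 0.8 (m+1)/(eta0 dx)`.

The run is refused unless the grid provides at least 10 cells per
wavelength in the optically densest tissue present. Steady state is
declared when the cycle-to-cycle RMS drift falls below 0.5% (minimum 20
carrier cycles, raised-cosine source turn-on over 3 cycles); the RMS
field is then accumulated over one final full cycle. Non-convergence is
an error, not a warning.

`compute_sar()` applies `SAR = sigma |E_rms|^2 / rho` voxel-wise;
`normalize_sar()` divides by the incident power density to give SAR* in
(W/kg)/(mW/cm^2), which is amplitude-invariant and can be rescaled to any
exposure. `average_sar_10g()` implements the IEEE C95.1-style localized
metric: centred cubes grown voxel-by-voxel until they enclose 10 g of
tissue (air excluded), mass-weighted averaging, maximum over the group.
The guideline permits several kernel shapes; the cube semantics here are
fixed by a brute-force oracle in the test suite. Note that 10 g of brain
is a cube of roughly 21 mm — small grids must hold that much mass or the
function errors.

The embedded **Mie series** (`mie_reference()`) provides the analytic
interior and exterior field of a homogeneous lossy sphere and is the
independent reference for the FDTD solver: at 2 mm resolution on a 5-cm
tissue-like sphere (eps_r 50, sigma 1.4 S/m, 1 GHz) the interior RMS
fields agree to a few percent (L2). The series is truncated per
Wiscombe's criterion with a floor of `ka + 10` and checked for term decay
to 1e-8; the optical theorem (extinction = scattering for lossless
spheres) is verified in the tests.

## Pulse heating

For pulses well under a millisecond, thermal diffusion is negligible
(brain thermal diffusivity 2e-7 m^2/s; `diffusion_negligibility()` gives
the dimensionless check) and the pulse-end rise is simply

    dT = PIN * SAR* * tau_d / cp

exactly linear in the power density and the duration. Mechanically the
temperature follows a linear ramp to `dT` at `t = tau_d` and is held
constant afterwards — conduction is orders of magnitude slower than the
acoustics. Heating is applied to gray matter, white matter and CSF; skull
heating is computed but, because bone's expansion coefficient is several
times smaller and its SAR low, the skull is mechanically inert in the
wave stage.

The reference intensity scale: SAR* of order 0.7 with `cp = 3600` gives
0.001 degC for 1e6 mW/cm^2 at 5 us — the same millidegree as 1e4 mW/cm^2
at 500 us.

## Thermoelastic wave propagation

Brain, CSF and ventricles are treated as fluid-like acoustic media: the
shear modulus of brain tissue is about five orders of magnitude below its
bulk modulus, and the response of interest is pressure-dominated. The
governing equations,

    dp/dt = -K div(v) + K beta dT/dt,      rho dv/dt = -grad(p),

are integrated with staggered-grid leapfrog at 0.9x the CFL bound, in two
geometries:

* `solve_spherical()` — 1D spherically symmetric, finite-volume
  divergence (exact for uniform expansion), ghost-mirror `v(0) = 0` at
  the origin, pressure-release or rigid outer boundary, 256 shells by
  default. Its radial eigenmodes `f_n = n c/(2a)` against the analytic
  values are the convergence gauge (well under 2% at 128 shells).
* `solve_cartesian()` — 3D heterogeneous, with per-face inverse
  densities encoding the boundary conditions: zero on rigid faces, the
  fluid-cell value at free (vacuum-facing) surfaces.

**Skull handling.** The default is a rigid boundary (zero normal
velocity), the conservative reading of a bone five times stiffer than
brain. It is, however, an *overestimate* of confinement: a slowly heated,
rigidly confined cavity supports pure compression and develops no
tensile focus at all. The `skull = "stiff_fluid"` option models the
skull as a non-expanding stiff fluid with cortical-bone density and wave
speed, whose outer surface is free — the analogue of an elastic skull
with little external confinement. The stress-focusing analyses in the
tests use this option, and with it the solver reproduces the canonical
tensile-peak sequence (frontal ~39 us, periventricular ~59 us, occipital
~161 us for a 5-us frontal pulse on the 0.17 m head), the front-to-back
sweep taking about `2 tau_c`.

Two closed-form limits bracket the dynamics and are asserted in the
tests:

* **Inertial confinement** (`tau_d << tau_c = a/c`): the stress
  magnitude is `K beta dT` (`inertial_confinement_pressure()`); both
  solvers hold this plateau exactly under uniform rapid heating.
* **Compatibility (equilibrium) limit** (`tau_d >> tau_c`): uniform and
  linearly varying temperature fields satisfy strain compatibility in an
  unconfined body, so residual stresses vanish; the solvers leave under
  5% of `K beta dT` for `tau_d = 50 tau_c`.

Between the limits, peak tensile pressure decreases monotonically with
`tau_d / tau_c` — the stress-focusing contrast between 5-us and 500-us
pulses of equal deposited energy.

Displacement is integrated on the faces alongside velocity; the maximum
principal logarithmic strain and principal strain rate are evaluated over
gray/white matter every few steps from central-difference gradients of
the centre-interpolated fields (closed-form symmetric-3x3 eigenvalues).
At millidegree loads strains are of order 1e-6 — far below any injury
threshold — which also justifies neglecting shear stiffness.

## Spectral analysis and injury metrics

`pressure_spectrum()` takes the one-sided FFT amplitude of a uniformly
sampled probe trace (rectangular window, 4x zero padding) and locates the
dominant peak above 1 kHz with parabolic interpolation. A 5-ms trace
gives 50-Hz padded bins — ample for the ~9.7 kHz fundamental of the
0.15-m brain sphere (`c/2a` with `c = 1450 m/s`).

On the idealized ellipsoid phantom the *set* of cavity frequencies is
independent of exposure direction, but which member dominates a given
probe can trade places between degenerate mode families as the load
rotates; the direction-invariance tests therefore assert that each
direction's dominant peak appears in the other's peak set (one FFT bin)
and that both lie in the microwave-auditory band, with exact one-bin
equality asserted on the spherical phantom where rotation symmetry makes
it well-posed.

`assess_injury()` compares extrema against one central table
(`injury_thresholds()`): cavitation at the conservative -100 kPa edge of
the -100 to -150 kPa band, the 18% axonal strain threshold (3-6% at high
rate), and the 20-120 kPa tensile band typical of instrumented football
head impacts. `power_sweep()` exploits the end-to-end linearity in PIN:
one reference pipeline run is rescaled, with an optional independent
wave-stage re-run as a nonlinearity check (deviation above 1% flags).
Exposure arithmetic (`erl_energy()`, `pulse_energy_density()`,
`power_density_at_range()`) places scenarios against the IEEE C95.1
reference limit `f_MHz/200` W/m^2 over 30 min: a 1-GHz, 5-us,
1.5e7 W/m^2 pulse carries 75 J/m^2, versus 9000 J/m^2 allowed over the
averaging window — the core of the "permissible yet potentially
injurious" observation.

## Problem sizes and numerical choices

Default desk-scale resolutions: 2 mm EM grid on a head-only domain
(about 100^3 cells including the 10-cell PML), 2.5 mm wave grid, 256
radial shells, 5 ms of simulated acoustics for spectra. The test suite
uses reduced geometries (a ~0.096 m outer-diameter head for pipeline
smoke tests, 3-5 cm spheres for solver validation) chosen so each
validation still has at least 10 cells per wavelength and several voxels
per layer. The pipeline is deterministic end to end — re-running a
scenario reproduces every artifact byte-identically; no stage uses
random numbers.

Degenerate inputs are errors, not silent defaults: under-resolved FDTD
grids, non-convergent steady states, CFL violations, probes outside the
domain, tissue groups lighter than the averaging mass, non-uniform trace
sampling, and non-positive power densities in `temperature_rise()` (a
zero-power *scenario* is still a valid pipeline input and
short-circuits to zero fields).

## What the synthetic phantom does and does not show

The layered ellipsoid reproduces the controlling scales of the problem —
head size, shell impedances, penetration depth of the deposition — so
characteristic times, mode frequencies, focusing behaviour, linearity
and threshold logic transfer. It does *not* reproduce realistic-anatomy
magnitudes: absolute kilopascal values, frequency-by-frequency SAR*
curves, or the anatomical location of hotspots depend on the segmented
geometry and measured property tables of a real head model and are
covered here only as trends (monotone power sweeps, deep-brain focusing,
direction-robust spectra). Also out of scope: vasculature and
thermoregulation, multi-pulse repetition regimes, viscoelastic or shear
constitutive behaviour, cavitation bubble dynamics, and the auditory
periphery.
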