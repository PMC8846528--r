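---
title: "Proton range monitoring from 13N activation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proton range monitoring from 13N activation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonrange)
```

## The problem

A therapeutic proton beam deposits most of its dose in a sharp Bragg peak
just before the protons stop, so millimetre-level uncertainty in the beam
range translates directly into dose misplacement. One non-invasive way to
verify the range is activation PET: the beam produces the positron emitters
11C, 15O and 13N in tissue, and their annihilation photons are imageable.
The key nuclear fact is that the 16O(p,2p2n)13N channel has a much lower
threshold (5.660 MeV) than the channels feeding 11C (20.61 MeV) and 15O
(16.79 MeV). Protons retain more than 5.660 MeV until a fraction of a
millimetre before they stop, so 13N is produced almost up to the end of
range and its depth profile forms a peak 1--2 mm proximal to the Bragg
peak, while 11C and 15O production dies off several millimetres earlier.
If the small, stable offset between the 13N peak and the Bragg peak is
calibrated as a function of beam energy, a measured 13N peak depth converts
into an estimated Bragg-peak depth.

`protonrange` implements this whole chain as desk-scale, fully tested code:
an analytic beam/phantom model that stands in for Monte Carlo transport, a
per-nuclide activation and decay simulator producing dynamic frames,
voxel-wise spectral analysis that isolates the 13N component from the
measured kinetics, peak localisation and the energy sweep of the offset,
and the interpolating calibration lookup.

## Beam and phantom model

The phantom is a homogeneous agar water-gel box (default
100 x 100 x 400 mm), density 1.010 g/cm^3, mass fractions H 11.00%,
C 4.650%, O 84.35%. Nitrogen is absent by construction, so no nitrogen
activation channels exist and all 13N comes from oxygen. The beam is a
monoenergetic pencil beam of diameter 10 mm along +z; depth is measured
from the entrance face. The air gap between nozzle and phantom is ignored
(proton energy loss in 25 cm of air is a fraction of an MeV and shifts all
depths equally).

The range--energy relation has two modes:

* **Bragg--Kleeman closed form** (default): R[cm] = alpha E^p in
  unit-density water with alpha = 0.0022, p = 1.77, scaled by 1/density.
  It is analytically invertible, which gives the residual energy E(z) in
  closed form and makes the residual-range identity
  R(E(z)) = R(E0) - z exact.
* **Tabulated stopping power**: numerical integration of a packaged mass
  stopping-power table for liquid water, computed from the Bethe formula
  with I = 75 eV and Z/A = 0.5551. The two modes agree within about 1% at
  80 MeV and within 3% across 45--250 MeV; the table is the independent
  oracle for the closed form in the test suite, not a second user-facing
  physics.

The depth-dose profile is built per bin as the residual-energy drop across
the bin edges divided by the bin width, so with straggling and fluence
attenuation off the profile integrates exactly to E0 (energy conservation
is a test, not an approximation). Two first-order corrections are applied:

* **Range straggling**: Gaussian convolution with
  sigma_R = 0.012 R^0.935 (R in cm), the standard analytic
  parameterisation. The same convolution is applied to the production
  profiles -- dose and activation ride on the same proton fluence, so
  letting only the dose straggle would bias the offset at high energy,
  where sigma_R reaches ~3.5 mm.
* **Nuclear removal**: fluence Phi(z) = exp(-z / Lambda) with
  Lambda = 1000 mm, a first-order plateau slope that does not materially
  move peak positions.

Depth bins default to 0.5 mm with centres at (k + 1/2) dz, matching the
0.5 mm quantisation of the published offset lookup (depths such as 29.5 or
81.5 mm).

## Activation model

Per-nuclide production is Y(z) = n_target sigma(E(z)) Phi(z), with
n_target proportional to (mass fraction)/A for the target element and the
overall scale left relative, as is conventional for per-primary-proton
tallies. The cross-section curves are packaged CSV fixtures encoding the
published excitation shapes: each is identically zero below its threshold,
and the 13N curve rises to a resonance of about 20 mb near 13 MeV before
settling to an approximately flat ~5 mb plateau above 37.5 MeV. The
near-threshold shape is the only part that moves peak positions; the
absolute scale cancels in every peak and offset. The 13N offset arises
naturally from this geometry: the residual range of a 13 MeV proton is
about 2 mm, so the yield maximum sits about 2 mm proximal to the stopping
point, truncated at the 5.660 MeV cutoff about 0.5 mm before it.

The (p,2p2n) channel is treated as one composite curve inclusive of
(p,alpha), and 11C production from oxygen is ignored; only the three
registry channels are modelled. Yield maps distribute the 1D profile
uniformly over the beam's disc footprint (voxel centres inside the disc),
so the lateral reduction returns the 1D profile bin for bin.

## Dynamics

Irradiation is treated as an impulse at t = 0: each voxel starts with a
fixed inventory N0 per nuclide and decays freely. Frames store expected
decay counts, N0 (e^(-lambda t1) - e^(-lambda t2)), on the schedule --
default 75 contiguous one-minute frames. No decay correction is applied;
the spectral stage consumes raw frame counts. Optional Poisson noise
replaces each voxel-frame count with a seeded draw of mean scale x count;
the seed is stored in the series metadata and the draw is bit-reproducible.

## Spectral analysis

Each voxel's time-activity curve is modelled as a non-negative combination
of decaying exponentials on a fixed grid of decay constants beta_j,
log-uniform from 1e-4 to 0.1 1/s with M = 1000 (half-lives ~7 s to ~2 h;
consecutive grid points differ by ~0.7%). The basis entries are
frame-averaged impulse responses,
(e^(-beta t1) - e^(-beta t2)) / (beta (t2 - t1)), because frames are
integrals of counts, not point samples. Amplitudes are solved per voxel by
non-negative least squares (Lawson--Hanson); no iteration or nonlinear
fitting is involved, which is what makes voxel-wise application cheap.

Two conventions matter and are deliberate:

* **Time origin**: basis times are referenced to the start of the first
  frame. Fitted amplitudes are therefore component activities at scan
  start. This is the only convention available for measured data (the
  scanner does not know the irradiation time), and it is what produces the
  published ROI orderings for delayed acquisitions: in a 15--75 min window
  the 2 min 15O has decayed by a factor ~150, so its amplitude at scan
  start is small even where its production was large.
* **Band readout**: grid discreteness splits one true exponential across
  adjacent grid points, so per-nuclide amplitudes are read as sums over
  beta bands with boundaries at the geometric midpoints of the registry
  decay constants (8.1e-4 and 2.56e-3 1/s) -- symmetric in log beta, the
  grid's own metric. A component's decay constant is reported as the
  amplitude-weighted mean beta within its band; on noiseless three-nuclide
  mixtures this recovers all three half-lives within one grid step.

The per-voxel statistic S_v = sum_j alpha_j beta_j weights amplitudes by
decay rate, enhancing the short-lived 13N/15O signal over the long-lived
11C background; voxels are kept where S_v exceeds a strict threshold
(default 1.5). The threshold is in the arbitrary count units of the
normalisation, so it is exposed as a parameter; noiseless synthetic runs
have an exactly zero background and any positive cut works.

## Peaks, offsets, calibration

Profiles are reduced along depth, and peaks are located as the global
argmax with ties broken toward the shallower bin; parabolic three-point
refinement is available but the default reports bin centres, matching the
0.5 mm quantisation of the published tables. The offset at one energy is
computed from the dose and 13N production profiles on one grid:
offset = Bragg depth - 13N depth. Swept over 45--250 MeV in 5 MeV steps
(42 energies), the default fixtures give offsets between 1.5 and 2.0 mm,
inside the published 1.0--2.0 mm band, with both peak depths strictly
increasing in energy.

The calibration stage interpolates a 42-row offset table against energy --
either the packaged published lookup or a table produced by the sweep --
independently for Bragg depth, 13N depth and offset, with either piecewise
linear interpolation or a natural cubic spline ("natural" reads the
published phrase "non-linear cubic spline" in the standard way; clamped
boundaries were considered and rejected for lack of derivative data at the
band ends). Both methods pass through every knot exactly. Evaluation
outside 45--250 MeV is a hard error rather than an extrapolation, because
offsets outside the simulated band are unvalidated. The 0.1 MeV export
grid has (250 - 45)/0.1 + 1 = 2051 rows, and the Bragg-depth estimator is
simply measured 13N depth + offset(E). The identity offset = Bragg - 13N
is exact at the knots and preserved everywhere by linear interpolation;
for the cubic it is verified on the export grid rather than enforced.

## Study conditions and problem sizes

The package's default conditions are those of the study it models: water-gel
composition as above, 1 cm pencil beams, 45--250 MeV in 5 MeV steps, 0.5 mm
depth bins, 1 min frames to 75 min, beta grid 1e-4--0.1 1/s with M = 1000,
S_v threshold 1.5. The worked 3D example and the test suite run a reduced
lateral phantom (20 x 20 mm, 5 mm lateral voxels) so that the ~400
voxel-wise NNLS fits of an 80 MeV study complete in seconds; the depth axis
keeps the full 0.5 mm resolution, which is the axis that carries the
science. The ROI analysis (whole / edge / plateau / Bragg-peak boxes,
defaults: first 10 mm; 20--80% of the Bragg depth; Bragg depth +/- 5 mm)
uses a 15--75 min acquisition window, the delayed 60 min dataset of the
imaging protocol it reproduces.

```{r roi-demo, eval = FALSE}
phantom <- phantom_spec(c(20, 20, 60), c(5, 5, 0.5))
beam <- beam_spec(80)
series <- build_frames(yield_map_3d(beam, phantom),
                       schedule = frame_schedule(60, 60, t0_s = 15 * 60))
fits <- fit_series(series)
bragg <- find_peak(depth_dose_profile(80))$depth_mm
rois <- default_rois(phantom, bragg)
spectrum_band_mass(roi_spectrum(fits, roi_mask(phantom, rois$peak)))
```

On this run the Bragg-region ROI is dominated by the 13N band (its mass
exceeds the 11C band by more than an order of magnitude), the plateau and
edge ROIs by 11C, and the SA-extracted 13N image peaks 1.5 mm proximal to
the Bragg peak -- the same structure the sweep produces from the yield
profiles directly.

## What the generator does and does not emulate

The synthetic data reproduce the features the method depends on: correct
range--energy scaling, a realistic Bragg peak with straggling, threshold
gating of the three production channels with the right cutoff ordering,
exact exponential kinetics on the frame schedule, and (optionally) Poisson
counting noise. They do not emulate Monte Carlo transport physics (nuclear
cascade models, secondary particles, lateral scattering), scanner effects
(attenuation, randoms, scatter, reconstruction, resolution blur), or
biological washout. Passing tests therefore demonstrate that the analysis
chain -- spectral separation, peak finding, offset calibration -- recovers
the truth its inputs contain; they do not certify the absolute offset
values for any particular scanner or patient geometry, where the
calibration table would be regenerated from measured or fully simulated
data by the same sweep.

## Numerical choices and edge cases

* NNLS is deterministic; an all-zero curve returns an all-zero spectrum
  with zero residual, and fits scale linearly with the input.
* Bin-averaged cross sections (8 sub-points per bin) integrate the fast
  sigma(E(z)) variation near the end of range instead of point-sampling it.
* Peak ties break toward the shallower depth; all-zero profiles are an
  error rather than a peak at an arbitrary position.
* Profile grids must cover the range plus a 6 sigma straggle tail; too
  short a grid is an error naming the required extent.
* Degenerate beta grids (M = 2) are the exact bounds; invalid bounds or M
  are errors.
* Energies outside 45--250 MeV are accepted by the beam model with a
  warning (the physics is smooth) but refused by the calibration lookup
  (the table is not).

## Limitations

The offset band reproduced here comes from an analytic model whose
cross-section fixtures encode published shapes, not evaluated nuclear
data; per-energy offsets should be read as the structure of the method,
not as dosimetric constants. Lateral physics is deliberately trivial
(uniform disc, no scattering), so only depth-axis quantities are
meaningful. Spread-out Bragg peaks, heterogeneous geometries and washout
modelling are out of scope.
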