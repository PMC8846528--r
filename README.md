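# protonrange

Proton-therapy range verification from positron-emitter activation imaging.

A proton beam stops in a sharp Bragg peak, and millimetre errors in the
predicted range misplace dose. Activation PET offers a non-invasive check:
the beam produces the positron emitters ¹¹C, ¹⁵O and ¹³N in tissue. Because
the ¹⁶O(p,2p2n)¹³N channel has a low threshold (5.660 MeV), ¹³N is produced
until just before the protons stop, and its depth profile peaks 1–2 mm
proximal to the Bragg peak — a stable, calibratable offset. `protonrange`
implements the full analysis chain for a water-gel phantom:

* **Beam/phantom physics** — Bragg–Kleeman range–energy model
  (R = αE^p, α = 0.0022, p = 1.77, density-scaled) with a Bethe-derived
  stopping-power table as the independent table mode; depth–dose profiles
  with Gaussian range straggling (σ_R = 0.012 R^0.935).
* **Activation** — per-nuclide yield profiles Y(z) = n·σ(E(z))·Φ(z) from
  threshold-gated cross-section curves, and 3D yield maps for a pencil beam.
* **Dynamics** — impulse irradiation at t = 0, closed-form decay counts in
  1-min frames to 75 min, optional seeded Poisson noise, NIfTI+CSV+JSON I/O.
* **Spectral analysis** — per-voxel non-negative least squares on a
  log-uniform grid of decaying exponentials (β from 10⁻⁴ to 0.1 s⁻¹,
  M = 1000), frame-averaged impulse-response basis, the S_v = Σ αⱼβⱼ
  statistic with a strict background threshold (default 1.5), nuclide bands
  at geometric midpoints of the decay constants, ¹³N component images and
  ROI spectra.
* **Range finding** — peak localisation (bin-centre or parabolic), the
  Bragg/¹³N offset at one energy, and the 45–250 MeV sweep in 5 MeV steps.
* **Calibration** — linear and natural cubic-spline interpolation of a
  42-row offset table at 0.1 MeV resolution, and the estimator
  Bragg depth = measured ¹³N depth + offset(E).

## Worked example

```r
library(protonrange)

## offset between the Bragg peak and the 13N peak at 80 MeV
compute_offset(80)
#>   energy_MeV bragg_mm n13_mm offset_mm
#> 1         80    50.25  48.75       1.5

## sweep the therapeutic band: 42 energies, offsets stay in 1.5-2.0 mm
sweep <- sweep_energies()
range(sweep$offset_mm)
#> [1] 1.5 2.0

## spectral analysis of one voxel: three nuclides, equal initial activities
sched <- frame_schedule()                    # 75 x 1 min frames
basis <- build_irf_basis(sched, make_beta_grid())
reg <- nuclide_registry()
tac <- Reduce(`+`, lapply(reg, function(n)
  decays_in_frames(1 / n$decay_constant_s, n$decay_constant_s, sched)))
band_summary(fit_voxel(tac, basis))
#>   nuclide alpha_sum beta_weighted half_life_min
#> 1     C11  60.00845  0.0005666965     20.385607
#> 2     N13  59.99339  0.0011593273      9.964790
#> 3     O15  59.99822  0.0056714059      2.036965

## calibration lookup at 0.1 MeV resolution
curve <- fit_interpolant(offset_table_fixture(), "linear")
offset_at(curve, 60)        # 1.5 mm at a knot
estimate_bragg(48.0, 80, curve)
#> [1] 50
nrow(export_grid(curve))
#> [1] 2051
```

The recovered half-lives (20.386, 9.965, 2.037 min) match the registry
values (20.39, 9.965, 2.037 min) within one grid step of the β grid
(~0.7 %); the recovered amplitudes (~60 per band) are the initial
activities × the 60 s frame length. A full 3D study — yield maps, dynamic
frames, voxel-wise fits, ROI spectra — is shown in the vignette
(`vignettes/range-monitoring.Rmd`); on a desk-scale 80 MeV run the
Bragg-region ROI is dominated by the ¹³N band, the plateau and edge ROIs by
¹¹C, and the SA-extracted ¹³N peak sits 1.5 mm proximal to the Bragg peak.

Command-line front-ends live in `inst/scripts/`:

```sh
Rscript inst/scripts/sweep.R --start 45 --stop 250 --step 5 --out offsets.csv
Rscript inst/scripts/peakcalib.R --method cubic --energy 127.3
Rscript inst/scripts/peakcalib.R --export-grid grid.csv
```

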