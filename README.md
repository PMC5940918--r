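# insituCDI

Simulation and reconstruction toolkit for **in situ coherent diffractive
imaging (CDI)** — lensless X-ray imaging of dynamic specimens in solution.

## The problem and who this is for

CDI records far-field diffraction intensities and recovers the lost Fourier
phases computationally. For a specimen that *changes* during the
measurement (dendrites growing in an electrochemical cell, organelles in a
live cell), every time frame yields one noisy diffraction pattern, and
conventional single-frame phase retrieval struggles: incomplete data,
missing centre, Poisson noise, stagnation in local minima.

In situ CDI splits the illumination with a dual-pinhole aperture into a
*dynamic* region `D_t(r)` (the specimen) and a *static* region `S(r)` (an
empty area or stationary structure). Every frame records the interference
of both, so the static region is a time-invariant real-space constraint
shared by the whole series. The package is aimed at computational imaging
researchers who want to simulate such experiments end-to-end, test the
reconstruction algorithm, and quantify resolution and radiation dose.

## What is implemented

* **Optics** — energy/wavelength conversion, tabulated X-ray optical
  constants (Pb, H2O, Au, average protein at 530 eV and 8 keV), dual-pinhole
  apertures, band-limited angular-spectrum propagation, geometry-derived
  quantities (reconstruction pixel `lambda z / (N p)`, full-period
  detector-edge resolution `2 lambda z / (N p)`, oversampling ratio
  `sigma1 = (lambda z / p) / a`).
* **Phantoms** — seeded generators: a growing dendrite series (Pb, <= 500 nm,
  in 1 um water), a lacey-gold static pattern (20 nm Au), a model cell
  (vesicle + protein aggregates, <= 1 um, in a 3 x 3 um region); conversion
  of thickness maps to complex transmission and to projected complex
  electron density.
* **Forward model** — expected counts
  `I_t(k) = I0 eta dt (r_e lambda / (a sigma1))^2 |F[P O_t]|^2`,
  a differential-flux two-region variant
  `eta dt (...)^2 {I_D |Psi_D|^2 + I_S |Psi_S|^2 + sqrt(I_D I_S)(Psi_D Psi_S* + c.c.)}`,
  sub-frame motion-blur integration, Poisson noise, missing-centre masking.
* **In situ reconstruction** — the simultaneous time-series algorithm: a
  weighted static blend `S' = gamma S_prev + (1-gamma) S_t` (gamma = 0.8)
  carried along frames, Fourier-magnitude projection with missing-centre
  pass-through, probe-weighted object update
  `O' = O + |P|P*/(alpha(|P|^2+eps)) (psi' - psi)` with `alpha = max|P|`,
  support splitting, per-sweep Fourier R-factor
  `R = sum||m|-|calc|| / sum|m|`; compiled core, seeded determinism.
* **OSS** — single-frame oversampling-smoothness retrieval (HIO + Gaussian
  low-pass of the off-support density, descending filter schedule), best of
  N runs by R-factor, optional a priori static-structure constraint.
* **Metrics** — Fourier ring correlation
  `FRC(k) = Re[sum Psi_a Psi_b*] / sqrt(sum|Psi_a|^2 sum|Psi_b|^2)` per
  ring, 1/e-threshold full-period resolution, absorbed dose
  `D = (P_t/A)(mu E / rho)`, fluence-reduction factors.
* **Pipeline** — presets, RDS/TIFF/CSV/YAML I/O, `cmd_simulate()` /
  `cmd_reconstruct()` / `cmd_evaluate()` and a thin CLI at
  `inst/cli/insitucdi.R`.

## Worked example

Simulate the desk-scale dendrite experiment (8 keV, 512^2 detector, 5 nm
reconstruction pixel, 5 frames of 10 x 1 ms sub-frames at
1e11 photons um^-2 s^-1, Poisson noise, 5 x 5 missing centre), reconstruct,
and evaluate:

```r
library(insituCDI)

study <- run_dendrite_study(dendrite_preset(desk = TRUE), seed = 1)
glance(study$recon)
#> # A tibble: 1 x 4
#>   n_frames n_iter final_r_factor share_static
#>      <int>  <int>          <dbl> <lgl>
#> 1        5    500          0.230 TRUE

average_frc_resolution(study$recon, study$stack)$resolution
#> # A tibble: 1 x 3
#>   resolution crossed threshold
#>        <dbl> <lgl>       <dbl>
#> 1    1.46e-8 TRUE        0.368
```

The R-factor falls from ~0.6 to ~0.23, the Poisson noise floor of this
photon budget (the floor, computed by comparing the true magnitudes with
the noisy measurement, is ~0.23 — R converges to the data, not below it).
The frame-averaged FRC against the known phantom crosses 1/e at ~15 nm
full-period resolution, approaching the 10 nm detector-edge limit of the
geometry (run time: about two minutes on one CPU).

Dose arithmetic for the soft X-ray study:

```r
dose_table(photon_energy = 530)
#> # A tibble: 4 x 2
#>   fluence   dose_gy
#>     <dbl>     <dbl>
#> 1  35000     2752.
#> 2 350000    27519.
#> 3 3500000  275189.
#> 4 35000000 2751887.
```

The dose-reduction study (`run_dose_study(dose_preset())`) reconstructs the
model cell with OSS at fluences 3.5e4-3.5e7 photons um^-2, with and without
the lacey-gold static structure (1.4e10 photons um^-2, known a priori), and
measures how much less fluence the assisted arm needs for the same FRC
resolution.

## Notes

* Objects are handled as projected complex electron density (electrons per
  pixel); see the methods vignette (`vignettes/insitu-cdi-methods.Rmd`) for
  the forward-model conventions, algorithm details, initialization, desk
  scaling, and known limitations.
* Everything stochastic (phantom growth, noise, initial phases) is
  reproducible from explicit seeds.
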