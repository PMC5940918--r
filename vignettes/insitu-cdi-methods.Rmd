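---
title: "In situ CDI: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In situ CDI: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The imaging problem

Coherent diffractive imaging (CDI) records the far-field diffraction
intensity of a coherently illuminated specimen and recovers the lost Fourier
phases computationally. For a *dynamic* specimen one pattern per time frame
is available, and conventional single-frame phase retrieval must solve each
frame independently — slow, and fragile against noise and missing data.

In situ CDI changes the experimental geometry: a dual-pinhole aperture
creates two illuminated regions on the sample plane. One pinhole covers the
evolving specimen (the *dynamic* region `D_t(r)`), the other a region that
does not change during the series (the *static* region `S(r)` — an empty
area or a stationary structure). Every frame's diffraction pattern records
the interference of both regions, so the static region is a time-invariant
constraint shared by all frames. The reconstruction exploits it to phase the
whole series simultaneously.

## Forward model

The object is represented as a projected complex electron density. A
thickness map `h_m(r)` per material `m` is converted with tabulated optical
constants (`delta`, `beta` at 530 eV and 8 keV, Henke/CXRO-style values
bundled in `optical_constants()`):

* complex transmission (thin-object projection approximation):
  `t(r) = exp(i (2*pi/lambda) * sum_m (-delta_m + i beta_m) h_m(r))`;
* projected electron count per pixel:
  `O(r) = (2*pi / (r_e lambda^2)) sum_m (delta_m - i beta_m) h_m(r) px^2`,
  which is exactly `(i/(r_e lambda)) log t(r) px^2`.

The exit wave is `psi_t = P * O_t` with `P` the illumination obtained by
angular-spectrum propagation of the binary dual-pinhole aperture to the
sample plane. Expected detector counts are

```
I_t(k) = I0 * eta * dt * (r_e * lambda / (N * dr))^2 * |F[psi_t]|^2
```

with unnormalized centred FFT `F`; `N*dr` (array extent) equals `a*sigma1`,
the illuminated extent times the linear oversampling ratio, so the prefactor
is the Thomson cross-section `r_e^2` times the detector-pixel solid angle.
With the object in electron units this yields physically scaled photon
counts (the electron-density representation is what makes the prefactor
meaningful; feeding a unit-modulus transmission through the same formula
would produce vanishing counts).

The differential-flux variant scales each region's amplitude by the square
root of its fluence, `|sqrt(I_D) Psi_D + sqrt(I_S) Psi_S|^2`, identical to
the expanded three-term form and manifestly non-negative; at equal fluences
it reduces exactly to the uniform model (asserted in the tests).

Detection adds, in order: sub-frame integration (each 10 ms frame is the sum
of 10 intensity patterns from 1 ms snapshots of the evolving phantom —
motion blur acts on intensity, since different instants are mutually
incoherent), Poisson noise (exact `rpois` draws up to 1e7 expected counts; a
rounded-normal approximation above, where its relative error is below
~3e-4 and exact sampling would overflow 32-bit integers), and a 5 x 5
missing centre whose pixels are flagged invalid and carry no constraint
during reconstruction.

## The reconstruction algorithm

Each iteration sweeps the frames in order. For frame `t`:

1. blend the running static estimate with the frame's stored one,
   `S' = gamma * S_run + (1 - gamma) * S_t`, `gamma = 0.8`;
2. form the object `O = S' + D_t` and exit wave `psi = O * P`;
3. replace the calculated Fourier magnitudes by the measured ones on valid
   pixels (missing-centre pixels keep their calculated values);
4. update the object with the probe-weighted correction
   `O' = O + |P| P* / (alpha (|P|^2 + eps)) (psi' - psi)`,
   `alpha = max|P|`, `eps = 1e-6 max|P|^2`;
5. clamp `O'` to the physical range of a projected electron density —
   non-negative real part (refractive decrement) and non-positive imaginary
   part (absorption), which holds for every bundled material
   (`density_range`, on by default; the classic positivity constraint of
   CDI expressed in density units, and the effective remedy against
   conjugate-twin ghosts on the centrosymmetric pinhole supports);
6. split `O'` onto the two supports (everything outside is set to zero) and
   carry the new static estimate to the next frame; after the last frame it
   wraps around into the next sweep.

The Fourier R-factor `R = sum || |m| - |calc| || / sum |m|` over valid
pixels is recorded every sweep. With Poisson-noisy data R converges to the
noise floor of the measurement, not to zero; convergence should be judged
by the trace flattening at that floor. At the photon budgets of the bundled
presets most detector pixels hold only a few photons, which puts that floor
near 0.23 (the tests compute it explicitly by comparing the true magnitudes
with the noisy measurement). The returned objects are the mean over the
final `average_window` sweeps (default 100), suppressing the
iteration-to-iteration noise fitting that the magnitude projection induces.

Support masks are the ideal pinhole discs dilated by 2 pixels (absorbing
propagation fringes); dilation is configurable. A control mode
(`share_static = FALSE`) disables the cross-frame constraint, giving
independent per-frame retrieval — used to demonstrate that the constraint
is what makes the series converge.

### Initialization

Fourier phases are drawn uniformly per pixel and frame, combined with the
measured magnitudes, inverse-transformed and divided by `P` where `|P|`
exceeds 10% of its maximum. On top of this random component the
initialization anchors on the *known empty-cell background*: in an immersion
experiment the water slab under both pinholes is known a priori, and its
projected density is a strong, smooth, low-frequency component of the true
object. The random component is scaled to the background's rms and added to
it. Diagnostics during development showed why this matters: the sweep is an
error-reduction-type projection algorithm, and from a purely random start it
stagnates (the two-region geometry admits near-degenerate twin
configurations); once either region is approximately known the joint problem
becomes holographic and converges rapidly. Anchoring on the background —
knowledge an experimenter always has — places the start inside that basin
while keeping runs seed-stochastic. `background = NULL` gives the pure
random start for comparison.

### Single-frame OSS

The dose-reduction study uses oversampling smoothness (OSS) phase retrieval
on single frames: a hybrid input-output update (`beta = 0.9`) inside the
support, with the off-support density low-pass filtered each iteration by a
Gaussian `W(k) = exp(-k^2 / (2 alpha_f^2))` whose width steps down linearly
from `N` to `N/10` over 10 stages; each stage restarts from the lowest-R
iterate so far, and the final result is the best of `n_runs` independent
random starts by Fourier R-factor. When the static structure is known a
priori (the assisted arm of the dose study), its complex density — scaled by
`sqrt(I_S / I_D)` to the measurement's amplitude normalization — is
re-imposed on its support every iteration.

## Phantoms

All generators are pure functions of (grid, parameters, seed).

* **Dendrite series** — biased random tip growth with branching inside the
  dynamic pinhole: tips advance with angular jitter, branch with fixed
  probability, and deposit discs whose arrival time sets a thickness ramp
  capped at 500 nm (Pb). Growth is strictly additive, so per-pixel thickness
  is non-decreasing. Each snapshot is smoothed with a sigma = 0.7 px
  Gaussian — the phantom is band-limited essentially at the grid Nyquist, so
  the resolution an ideal reconstruction can demonstrate is the
  detector-edge value.
* **Lacey gold** — level-set ridges of a smoothed Gaussian random field,
  thresholded at a quantile to impose the fill fraction exactly, times a
  uniform 20 nm thickness.
* **Model cell** — a ~2 um elongated organelle with a dome thickness profile
  plus scattered aggregates of average-protein composition
  (H50C30N9O10S1, 1.35 g cm^-3), total thickness capped at 1 um, confined to
  a central 3 x 3 um region, in 1 um of water.

What the generators do *not* emulate: real electrochemistry (growth rates,
crystallography), organelle ultrastructure, container scattering, partial
coherence, or detector readout noise. Passing tests therefore demonstrate
the *method* — forward model plus reconstruction — on objects with realistic
contrast, scale and dynamics, not fidelity to any particular specimen.

## Study presets and problem sizes

Two presets reproduce the package's headline experiments; the desk variants
are the default test scale.

* `dendrite_preset()` — 8 keV, flux 1e11 photons um^-2 s^-1, detector
  efficiency 0.8, 100 Hz frames from 10 x 1 ms sub-frames, 5 x 5 missing
  centre. Full scale: 1024^2 detector, 1 um pinholes spaced 1.25 um,
  ~5.9 nm reconstruction pixel, sigma1 ~ 2.7. Desk scale: 512^2 with the
  aperture and phantom scaled by 0.4 (0.4 um pinholes spaced 0.5 um), chosen
  so that both the reconstruction pixel (5 nm) and the oversampling ratio
  (~2.8) match the full geometry — the resolution claim is pixel- and
  sampling-limited, so preserving those two quantities preserves the claim
  while the array shrinks. 5 frames, 500 sweeps.
* `dose_preset()` — 530 eV, 10 um detector pitch at 5 cm, 3 um pinholes
  spaced 4 um, exposure 1 s, dynamic-region fluence ladder
  3.5e4-3.5e7 photons um^-2, static-region fluence 1.4e10. Full scale:
  1100^2 (detector-edge resolution 21.2 nm). Desk scale: 550^2, same field
  of view with a doubled (42.5 nm) reconstruction pixel; OSS runs 300
  iterations x 5 starts per condition.

## Numerical choices

* Centred FFT convention: origin at pixel `floor(N/2)+1`; `fftshift` /
  `ifftshift` are exact inverses for any N. The compiled cores work in
  unshifted ordering internally; magnitudes are invariant to the input
  shift, so the two conventions agree bit-for-bit (asserted against a
  pure-R reference sweep).
* Propagation uses the band-limited angular spectrum: exact identity at
  distance 0, unitary on the propagating band (the geometries used never
  sample evanescent frequencies), with a sampling-adequacy warning.
* Aperture rasterization: a pixel is open when its centre is inside the
  disc; no anti-aliasing, for bit-reproducibility.
* Magnitude projection guards `|F| = 0` pixels by substituting the measured
  magnitude at zero phase.
* FRC is the standard conjugated, ring-summed form (rings of 1 px width);
  the resolution is read where the 3-ring median-smoothed curve first stays
  below the threshold for 2 consecutive rings (robust against single-ring
  dips), in the full-period convention; a curve that never crosses reports
  the detector-edge resolution, flagged. The series-level number is the 1/e
  crossing of the frame-averaged curve.
* Dose: `D = fluence x (mu/rho) x E`, with photons um^-2 converted to cm^-2,
  eV to J, and J g^-1 to Gy (x1000), so the arithmetic is bit-reproducible.
* Registration for scoring single-frame reconstructions tests the identity
  and the conjugate inversion over integer circular shifts (FFT
  cross-correlation) and aligns the global phase. The in situ series is
  scored without registration: the known illumination pins the object.
* All stochastic steps (phantom growth, Poisson draws, initial phases)
  consume seeds explicitly and restore the caller's RNG state.

## Known limitations

* The iterative sweep needs the background anchor described above; with
  `background = NULL` it reproduces the textbook random start, which
  stagnates on the dual-region geometry within practical iteration budgets.
* The illumination is assumed known exactly; probe refinement is out of
  scope.
* The rounded-normal branch of the Poisson sampler is an approximation
  (entirely adequate above its 1e7-count threshold).
* Optical constants are bundled approximate tabulations; the dose-critical
  protein values (mu = 1.25e4 cm^-1, rho = 1.35 g cm^-3 at 530 eV) are the
  reference ones.
* At the desk photon budget the Poisson floor of the R-factor is well above
  zero; R is a convergence monitor, not an image-quality metric — image
  quality is always quantified by FRC against the known phantom.
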