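---
title: "Quantitative phase-contrast densitometry with a simulated Talbot interferometer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative phase-contrast densitometry with a simulated Talbot interferometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaseCT)
```

## The model

A two-grating Talbot interferometer measures refraction rather than
absorption. A phase grating G1 (pitch d, π/2 phase shift at its design
energy) forms an intensity self-image at the fractional Talbot distance
z_Talbot = p d²/(2λ) for odd order p; an absorbing analyser grating G2 at
that distance converts lateral fringe displacements into intensity
changes. A sample upstream of G1 refracts the beam by an angle equal to
the transverse derivative of its projected phase, which displaces the
fringes; stepping G2 through N equally spaced sub-period positions turns
each detector pixel into a sampled sinusoid

I_k = I₀ [1 + V cos(2πk/N + ψ)],  k = 0 … N−1,

whose phase ψ = (2π z_T / d₂) ∂t_δ/∂x encodes the derivative of the
projected refractive-index decrement t_δ = ∫ δ ds, and whose relative
first-harmonic amplitude V is the fringe visibility. Tomographic
reconstruction of ψ-sinograms with a Hilbert-type filter yields
Δδ = δ − δ_medium per voxel, and the decrement is proportional to mass
density,

δ = r_e λ² N_A (Z/M) ρ / (2π),

with r_e = 2.8179 × 10⁻¹⁵ m, N_A = 6.022 × 10²³ mol⁻¹ and Z/M ≈ 0.55 for
soft tissue, so ρ = ρ_w + Δρ relative to the surrounding saline.

Model assumptions, all of which the simulator shares with the desk-scale
analysis it supports:

- **Parallel beam.** A synchrotron bending-magnet station a few hundred
  metres from the source is quasi-parallel; projection and backprojection
  use parallel geometry with a vertical rotation axis.
- **Geometrical phase transfer.** The self-image is not propagated with
  Fresnel diffraction; the stepping curve is synthesized directly from
  (transmission, ψ, V). Partial coherence enters only through the
  visibility parameter and the sine-vs-triangle profile choice.
- **1/E phase-shift scaling.** The grating phase shift is scaled from the
  design energy as φ ∝ 1/E (δ ∝ λ²), valid away from absorption edges of
  the grating material.
- **Linear attenuation.** Absorption is a single proportionality
  constant (mu per unit density, default 0.05 mm⁻¹ per g cm⁻³, about
  water at 25 keV). Attenuation only sets photon statistics here; phase
  is the signal, and the package deliberately embeds no attenuation
  database — Beer–Lambert budgets take caller-supplied coefficients.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| energy | 25 | keV | sets λ = hc/E and hence z_Talbot and the δ–ρ constant |
| grating pitch d | 10 | µm | z_Talbot = p d²/(2λ); phase sensitivity 2π z_T/d₂ |
| Talbot order p | 3 | — | odd; distance scales linearly |
| G2 tilt | 45 | deg | Δz = (extent/2) sin(tilt); achromaticity Δλ/λ = 2Δz/z_T |
| effective pixel | 15.5 | µm | detector sampling; an override exists because the quoted object-plane pixel (15.5) differs from native/magnification = 6.5/0.425 = 15.29 |
| N_step | 5 | — | stepping samples per period; 3 is the minimum |
| exposure/readout/settle | 0.5 / 0.05 / 0.03 | s | trigger spacing; T = N × sum |
| visibility V | 0.3 | — | fringe contrast; phase noise ∝ 1/(V √photons) |
| photon budget | ∞ (noiseless) | photons/pixel/frame | Poisson statistics; 860 photons ≈ a 100 ms exposure behind the water cell |
| Z/M | 0.55 | — | soft-tissue electrons per molecular weight |
| calibration | 1.0 (simulation), 1.45 (instrument mode) | — | multiplicative factor on measured Δδ; a real detector's calibration is instrument-specific and opaque, the simulator has no bias to calibrate |
| ρ_w | 1.005 | g cm⁻³ | normal saline; the phase reference |

The wavelength carries an explicit rounding convention: the quoted
instrument numbers (3024 mm, 5.8 × 10⁻³, 2.9 × 10⁻⁴ nm) reproduce exactly
when λ(25 keV) is rounded to 3 significant figures (0.0496 nm), so
`energyToWavelength()` exposes `"full"` and `"3sf"` modes, and reporting
rounds distances to the nearest mm, shifts to 2 significant figures and
fields of view to 0.1 mm.

The scheduler truncates the rotation speed X_proj/T to whole pulses per
second (150/2.9 = 51.7 → 51), which reproduces the quoted 51 pulses/s
and a 29.4 min scan. Exact integer truncation makes the three-step to
five-step time ratio slightly less than 3/5 (1046.5/1764.7 = 0.593); with
the untruncated speed the rotation-limited time equals Y·T and the ratio
is exactly 3/5. `totalTime(roundSpeed =)` exposes both conventions; the
package treats the truncated one as the wall-clock prediction and the
exact one as the scaling law. One flat-field block is emitted at t = 0
plus one per completed flat interval (the initial block is configurable,
`initialFlat`); per-block stage-translation overhead defaults to 0 s and
is configurable, because published wall-clock totals that exceed the
rotation-limited time do not decompose that overhead.

## What the synthetic phantoms emulate

`makeFetusPhantom()` builds a nested-ellipsoid body (body, liver,
brain-like compartments) in saline. Defaults: body 1.025, brain 1.035,
liver 1.055 g cm⁻³. The fixed state shrinks the liver isotropically about
its centroid by 35% in volume and raises every tissue compartment by
0.015 g cm⁻³ — the middle of the 0.01–0.02 g cm⁻³ band reported for
formalin fixation — which puts the fixed liver at 1.07 g cm⁻³, where the
fixed-state histogram grows its new peak. No absolute fresh-liver density
is available from the literature the defaults emulate; they are
parameters, not claims.

`makeAortaPhantom()` builds an annular tube with two wall layers (intima
1.045, externa 1.060 g cm⁻³). Each stretch step elongates the tube by 8%
and thins the wall with layer mass conserved while the density rises
linearly to a configured 0.004 g cm⁻³ total over five steps (under the
<0.005 g cm⁻³ scale of stretched-vessel observations). Conservation is
engineered discretely: the tube length snaps to whole slices and layer
membership is assigned in radius order until the voxel count that
conserves mass at the new density is met exactly, with a sub-voxel centre
offset lifting lattice-radius ties. In-grid layer mass is constant to
<0.1% across steps.

What these phantoms do **not** contain: anatomical texture, internal
density gradients, motion or deformation during the scan, fixative
diffusion kinetics, strain fields. Passing the recovery suites therefore
shows that the *measurement chain* is unbiased and correctly scaled at
realistic contrast and geometry — not that real organs would be
segmented or resolved equally well.

## Numerical choices

- **Projector/backprojector.** Compiled rotate-and-sum with bilinear
  interpolation (step = one voxel along the ray), and linear
  interpolation in the backprojection; angles cover [0°, 180°).
- **Derivative.** Central differences with pixel-pitch spacing
  (one-sided at the edges). Objects touching the lateral grid edge
  trigger a warning because the derivative is undefined there.
- **Filter.** The discrete filters are the DFTs of band-limited spatial
  kernels — the Ram-Lak kernel for the ramp route and, for derivative
  data, the kernel with h(k) = 1/(π²kΔ) for odd k and 0 otherwise, the
  truncated inverse transform of sgn(f)/(2πi). Sampling |f| or sgn(f)
  directly on the DFT grid misweights the lowest frequencies and biased
  the reconstructed interior by ≈4% in development; the kernel form
  recovers a homogeneous cylinder's interior to 0.01%. Rows are
  zero-padded to the next power of two; a Hann window closes at the
  Nyquist frequency (default on — unwindowed sign filters amplify noise).
- **Sign conventions.** ψ is positive where δ increases toward +x on the
  detector; the reconstruction uses the matching sign so tissue denser
  than saline reconstructs positive.
- **Wrapping.** Retrieval phases and flat-field differences are wrapped
  to (−π, π]; a row-wise 1-D unwrapper exists for strongly refracting
  edges but is not needed at soft-tissue contrasts (|ψ| ≲ 0.1 rad here).
- **Retrieval degeneracies.** Zero-intensity pixels are flagged invalid
  and propagate as NA through flat-field correction rather than NaN
  arithmetic.
- **Statistics.** Sample (n−1) standard deviations throughout; histogram
  modes are local maxima above 5% of the tallest bin (peak detection "by
  eye" needs a threshold to be reproducible).
- **Determinism.** Phantom generators are pure functions of their
  parameters; all Monte-Carlo stages take explicit seeds, and the
  pipeline derives per-stage seeds from one config seed by stable stage
  labels (kept below 2³¹).

## Design decisions that were genuinely open

- **Flat-field reference selection.** With measured data the nearest
  flat block in angle would be divided out; the simulator generates a
  per-angle reference (trans = 1, ψ = 0) and corrects each angle against
  its own, which is the same operator with a zero-distance reference.
  No temporal interpolation is attempted because acquisition protocols
  state only a fixed flat interval.
- **Dark-field channel.** The visibility ratio V_s/V_r is computed and
  stored but not analysed further; scattering contrast is outside the
  model.
- **Triangle-profile check.** The 8/π² first-harmonic factor of a
  triangle stepping curve is verified with N = 24 steps: at N = 5 the
  triangle's 9th and 11th harmonics alias onto the first-harmonic bin
  and shift the retrieved visibility by ≈0.9%, so a dense stepping
  isolates the Fourier property from sampling aliasing.
- **Ring-artefact score.** Standard deviation of the polar-angle-averaged
  radial profile in a background annulus (default 0.6–0.9 of the
  half-side). It is rotation invariant, near zero for noiseless
  reconstructions, and responds to detector-pixel-correlated
  perturbations; in a Poisson-only simulation it decreases with photon
  budget, which is the qualitative behaviour the exposure study checks.

## Problem sizes and what the suites show

The test and acceptance suites run the full chain at 64-voxel grids
(0.1 mm voxels, 6.4 mm field), 120–600 projection angles, with thin
slabs where slices are independent (parallel geometry makes an 8-slice
slab of a 64² cross-section reconstruct identically to the full cube).
At these sizes:

- the noiseless round trip (project → step → retrieve → reconstruct) on
  a Δδ = 7.3 × 10⁻⁹ cylinder (0.02 g cm⁻³ at 25 keV) recovers the
  interior to ≈0.01%, and the Hilbert route agrees with the
  integrate-then-ramp route to ≈0.2% RMS of the contrast;
- the fresh-vs-fixed pair recovers the injected 0.015 g cm⁻³ liver
  increment to ±0.0002 and the 0.65 volume ratio to ±0.001 (threshold
  segmentation at the body/liver density midpoint within the liver
  bounding box);
- the stretched ring recovers monotone density growth; the recovered
  total increment (≈0.0024 of the configured 0.004 g cm⁻³ at 64³) is
  compressed by partial-volume averaging over the thinning 3–5-voxel
  wall — at 96³ it rises to ≈0.0033. This resolution-limited
  under-recovery of thin-structure increments is a real property of the
  measurement, not an artefact of the tests;
- with Poisson noise at 860 photons·(exposure/100 ms) per pixel per
  frame, the background density resolution improves from ≈4.1 to
  ≈1.8 mg cm⁻³ between 100 ms and 500 ms exposures, following
  1/√exposure within a noise-independent discretization floor — the
  low-mg cm⁻³ regime of real instruments of this class.

## Known limitations

- No Fresnel/partial-coherence wavefield propagation; visibility maps,
  grating imperfections and the phosphor MTF are out of scope (an
  optional Gaussian blur stage stands in for detector blur, default
  off).
- No cone-beam geometry, no iterative reconstruction, no motion or
  deformation during a scan.
- Segmentation is deliberately minimal (global threshold within a
  region); organ masks are inputs everywhere else.
- The detector calibration factor (1.45 in instrument mode) is an opaque
  scalar: it cannot be re-derived from first principles here and the
  simulator's self-consistent mode uses 1.0.
- Printed water-cell transmissions of the emulated instrument (34% at
  25 keV) are not reproduced by Beer–Lambert with standard water
  coefficients (≈28%); transmission budgets therefore always take
  caller-supplied coefficients and no transmission value is asserted.
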