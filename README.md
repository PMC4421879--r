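# phaseCT

Desk-scale simulation and analysis chain for X-ray Talbot
grating-interferometer phase-contrast tomography of soft tissue.

Biological soft tissue is nearly transparent to hard X-rays: absorption
contrast is poor, but the refractive-index decrement δ (with
n = 1 − δ + iβ) is ~10³ times larger than β, so phase-sensitive imaging
resolves density differences of a few mg cm⁻³. A two-grating Talbot
interferometer measures the transverse derivative of the projected phase:
a π/2 phase grating G1 forms a self-image at the fractional Talbot
distance

    z_Talbot = p d² / (2 λ),   p odd,

where an absorbing analyser grating G2 converts sub-pixel fringe shifts
into intensity modulation. Stepping G2 through N sub-period positions
gives a per-pixel sinusoid I₀ [1 + V cos(2πk/N + ψ)]; the stepping-curve
phase ψ is proportional to ∂/∂x of the projected decrement. Filtered
backprojection with a Hilbert-type kernel (the ramp filter divided by the
derivative response) reconstructs Δδ = δ − δ_medium directly, and the
linear relation

    δ = r_e λ² N_A (Z/M) ρ / (2π)

converts it to mass density (Z/M ≈ 0.55 for soft tissue), so that
ρ = ρ_w + Δρ with ρ_w the density of the surrounding saline.

The package provides, as S4 classes and camelCase functions:

- **instrument** — closed-form design calculators: wavelength, Talbot
  distances, tilted-analyser geometry and achromaticity, grating phase
  shift vs energy, detector geometry, Beer–Lambert transmission budgets.
- **scheduler** — on-the-fly acquisition model: stepping period
  T = N(exposure + readout + settle), rotation speed in motor pulses per
  second, trigger timeline with flat-field blocks, total-time prediction.
- **phantoms** — synthetic voxel phantoms: a fetus-like nested-ellipsoid
  body (fresh and formalin-fixed states; fixation shrinks the liver and
  raises tissue density) and a two-layer vessel ring thinning under
  stepwise stretch with layer mass conserved.
- **forward_model / retrieval / reconstruct** — parallel-beam projection,
  phase-stepping frame synthesis with visibility and Poisson photon
  noise, first-harmonic retrieval with flat-field correction, and
  Hilbert-filter FBP (compiled projector/backprojector).
- **densitometry** — Δδ→ρ conversion with a detector calibration factor,
  ROI statistics, histograms with mode detection, compartment
  volume/mass, background density resolution, and an exposure-series
  quality study.
- **pipeline / CLI** — a YAML-configured, re-entrant, seeded pipeline
  (`runPipeline()`) writing TIFF stacks with JSON sidecars, plus a thin
  command-line wrapper in `inst/scripts/phasect.R`.

## Worked example

```r
library(phaseCT)

## instrument design at 25 keV
lam <- energyToWavelength(25, "3sf")          # 0.0496 nm
talbotDistance(10, lam, 3)                     # 3024.194 mm
tiltSpan(25, 45)                               # 8.838835 mm
achromaticShift(8.84, 3024, lam)$relativeShift # 0.005845
rotationSpeed(scanProtocol(600, 5, 0.5))       # 51 pulses/s

## simulate and analyse a fresh-vs-fixed fetus pair
fresh <- makeFetusPhantom(scenarioParams("fetus_fresh", n = 64))
beam  <- beamSpec(25, rounding = "3sf")
geom  <- geometrySpec(beam,
                      gratingSpec(10, "phase", designEnergy = 18.8,
                                  designPhaseShift = pi/2),
                      gratingSpec(10, "absorption", tilt = 45))
opt   <- densityToOptical(fresh, beam)
proj  <- projectVolume(opt, geom, 10, seq(0, 179.7, by = 0.3))
stack <- simulateStepping(proj, photonBudget = Inf, visibility = 0.3)
ret   <- retrieveStack(stack)
dvol  <- fbpDpc(ret, wavelength = beam@wavelength)
rho   <- deltaToDensity(dvol,
           densityConversion(beam@wavelength, 0.55, 1, 1.005))
roiStats(rho, labelMap(fresh) == 2L)$mean      # liver: 1.051187 g/cm^3
densityResolution(rho, labelMap(fresh) == 0L)  # 1.0227 mg/cm^3 (edge ringing,
                                               # no photon noise)
```

With the fixed-state phantom (`"fetus_fixed"`, 35% liver shrinkage,
+0.015 g cm⁻³ fixation increment) the same chain recovers a liver density
increment of 0.0148 g cm⁻³ and a liver volume ratio of 0.650 — the
injected study conditions — from the reconstructed volumes alone.

An end-to-end run from a config file:

```r
runPipeline(system.file("extdata", "demo-config.yaml",
                        package = "phaseCT"),
            out = "demo_out")
```

writes `phantom.tif`, stepping frames, retrieved sinograms, the Δδ
volume, a per-compartment `report.csv` and a `manifest.json` with
checksums; reruns with the same seed are byte-identical.

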