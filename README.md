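# rofl — Robust Orientation Fitting via Least Squares for 3D-PLI

`rofl` models, simulates and fits the light-intensity signals measured by
**3D-Polarized Light Imaging** (3D-PLI) of unstained brain sections on a
tiltable specimen stage.

3D-PLI exploits the birefringence of myelinated nerve fibers: rotating a
polarizer pair through angles ρ while imaging the transmitted light yields,
per pixel, a sinusoidal *rotation profile*

    I(ρ) = I_T/2 · (1 + sin(2(ρ − φ)) · sin δ),    sin δ = sin(π/2 · d · cos²α)

whose phase gives the in-plane fiber **direction** φ and whose amplitude — the
retardation |sin δ| — entangles the out-of-plane **inclination** α with the
**relative thickness** d (a myelin-density proxy). A planar view alone cannot
separate α from d, nor determine the sign of α. Tilting the stage by a small
angle τ towards four azimuths (N/E/S/W) views the same fiber from slightly
different angles and breaks the degeneracy; refraction at the tissue surface
reduces the 8° stage tilt to an internal τ = arcsin(sin 8°/1.45) = 5.51°.

The package provides:

* **Geometry** — orientation/vector conversion, tilting rotations, Snell
  correction, half-sphere symmetrization (`orientationToVector`,
  `tiltRotationMatrix`, `snellInternalAngle`, `symmetrizeOrientation`, …).
* **Forward model** — noise-free tilting profiles and their normalized form
  (`intensityProfile`, `normalizedModel`, `retardation`).
* **Noise model** — calibrated overdispersed camera counts, variance = 3 ×
  mean, as a negative binomial (`sampleIntensity`), plus the propagated
  variance of normalized intensities that defines the fit weights
  (`normalizedVariance`).
* **Modalities** — harmonic extraction of transmittance, direction and
  retardation from a profile (`extractModalities`).
* **ROFL fitter** — per-pixel weighted least squares: analytic Fourier
  direction, 6×6 brute-force (α, d) initialization, unbounded
  Levenberg–Marquardt refinement, symmetrization back into φ ∈ [0°, 180°),
  α ∈ [−90°, 90°], d ≥ 0 (`fitPixel`, `fitImage`). Fitted d > 1 and χ²
  outliers flag pixels (e.g. fiber crossings) the single-fiber model cannot
  describe.
* **Simulation studies** — Monte-Carlo accuracy surfaces over (α, d), and an
  inclination-bias study on orientations sampled uniformly on the sphere
  (`runAccuracyStudy`, `runUniformStudy`, `generatePhantom`).
* **I/O + CLI** — TIFF/JSON stack and parameter-map directories
  (`writeStack`, `readStack`, `writeMaps`, `readMaps`) and a command-line
  front end (`inst/scripts/rofl`) with `snell`, `fit`, `simulate-study` and
  `phantom` subcommands.

See the methods vignette (`vignettes/rofl-methods.Rmd`) for the full model,
estimator and validation description.

## Worked example

Simulate one noisy pixel of a standard acquisition (18 polarizer steps of
10°, planar + N/E/S/W views at 5.51° internal tilt, 2500-count profile mean,
gain 3) and fit it back:

```r
library(rofl)

acq <- pliAcquisition()
acq
#> PLIAcquisition: 18 polarizer angles (step 10 deg), 5 stage positions
#>   transmittance 2500 counts, gain 3, refractive index 1.45
#>   tilts: planar(psi=0,tau=0) N(psi=0,tau=5.51) E(psi=90,tau=5.51) S(psi=180,tau=5.51) W(psi=270,tau=5.51)

series <- simulateSeries(phi = degToRad(101), alpha = degToRad(-60), d = 0.5,
                         acq, seed = 42)[[1]]
seriesModalities(series)   # per-view Fourier modalities (radians)
#>    label transmittance direction retardation
#> 1 planar      5003.444  1.796362   0.1876336
#> 2      N      4987.667  1.949924   0.2096546
#> 3      E      4963.778  1.818959   0.1271490
#> 4      S      5040.556  1.610051   0.1886489
#> 5      W      4990.222  1.728487   0.2846940

fit <- fitPixel(series)
fit
#> PixelFit: phi = 101.88 deg, alpha = -63.39 deg, d = 0.6237 (chi2 = 279.99, R2 = 0.958)

evaluateFit(list(phi = degToRad(101), alpha = degToRad(-60), d = 0.5), fit)
#> gamma_deg   sigma_d
#> 3.4151382 0.2474215
```

The planar retardation alone (0.188) is compatible with many (α, d) pairs;
the four tilted views pin the fiber to 3.4° of the true axis, including the
inclination sign. A small accuracy surface:

```r
runAccuracyStudy(alphaDeg = c(0, 40, 80), d = c(0.3, 0.9), reps = 200, seed = 7)
#>   alpha_deg   d mean_gamma_deg mean_sigma_d   n
#> 1         0 0.3       3.040168  0.011280516 200
#> 2         0 0.9       1.275888  0.007130512 200
#> 3        40 0.3       2.918320  0.081994371 200
#> 4        40 0.9       1.038104  0.029708565 200
#> 5        80 0.3       5.744685  0.580128099 200
#> 6        80 0.9       1.409145  0.181725170 200
```

Orientation errors are ~1° for strongly myelinated fibers and grow where the
signal fades (small d, steep α); thickness errors grow towards α = 90°,
where d is nearly unidentifiable.

Whole images go through `fitImage()` (parallel, deterministic) or the CLI:

```sh
rofl=$(Rscript -e 'cat(system.file("scripts", "rofl", package = "rofl"))')
Rscript $rofl snell --tilt-deg 8 --refractive-index 1.45    # 5.5078
Rscript $rofl phantom --height 16 --width 16 --seed 1 --out /tmp/stack
Rscript $rofl fit --input /tmp/stack --out /tmp/maps
```

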