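---
title: "Methods: fitting 3D fiber orientations from tilting 3D-PLI measurements"
author: "rofl package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fitting 3D fiber orientations from tilting 3D-PLI measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rofl)
```

## The measurement and its signal model

3D-Polarized Light Imaging (3D-PLI) shines linearly polarized light through
unstained, microtome-cut brain sections and images the transmitted intensity
while a polarizer pair rotates through angles $\rho_i$. The myelin sheaths of
nerve fibers are birefringent, so each pixel produces a sinusoidal *rotation
profile*

$$ I_i \;=\; \frac{I_T}{2}\Bigl(1 + \sin\bigl(2(\rho_i - \varphi)\bigr)\,
   \sin\delta\Bigr), \qquad
   \sin\delta = \sin\Bigl(\frac{\pi}{2}\, d \cos^2\alpha\Bigr), $$

whose phase encodes the in-plane fiber *direction* $\varphi \in [0°, 180°)$
and whose relative amplitude — the *retardation* $|\sin\delta|$ — mixes the
out-of-plane *inclination* $\alpha \in [-90°, 90°]$ with the *relative
thickness* $d \ge 0$ (section thickness × birefringence / wavelength, a proxy
for local myelin density). $I_T/2$ is the mean transmitted intensity
(`transmittance()` of a `PLIAcquisition`, in camera counts).

A single planar view cannot separate $\alpha$ from $d$: a steep thick fiber
and a flat thin one produce the same amplitude, and the sign of $\alpha$ is
invisible. A tiltable specimen stage breaks this degeneracy. Tilting the
section towards azimuth $\psi$ by angle $\tau$ rotates every fiber axis by

$$ R(\psi, \tau) = R_z(\psi)\, R_y(\tau)\, R_z(-\psi), $$

so the four oblique views (N, E, S, W at $\psi = 0°, 90°, 180°, 270°$) see
the same fiber at four slightly different effective orientations — enough to
resolve both the inclination magnitude and its sign. Refraction at the tissue
surface reduces the stage tilt inside the section
(`snellInternalAngle()`): an 8° stage tilt at tissue refractive index 1.45
acts as $\tau = \arcsin(\sin 8° / 1.45) = 5.51°$. The default
`pliAcquisition()` describes this standard protocol: 18 polarizer steps of
10°, a planar view plus four oblique views at 5.51° internal tilt, 2500
counts expected profile mean and camera gain factor 3.

### Why the transmittance default is the profile mean

The signal model is parameterized by $I_T/2$, the *expected profile mean*.
All simulation defaults in this package set that mean to 2500 counts (slot
`transmittance`). This is the interpretation under which the package's
Monte-Carlo accuracy surfaces reproduce the published reference results it
was validated against; interpreting the 2500 counts as $I_T$ (profile mean
1250) doubles every simulated error, which is inconsistent with those
reference numbers.

## Noise model

Camera counts are overdispersed: the count variance grows linearly with the
mean, $\sigma^2 = g\,\mu$, with gain factor $g = 3$ for the calibrated
system. `sampleIntensity()` draws from a negative binomial with
$\text{size} = \mu/(g-1)$ and $\text{prob} = 1/g$, which has exactly this
mean and variance (the size is real-valued; R's `rnbinom()` samples the
underlying gamma–Poisson mixture, well defined for any positive size).

Before fitting, each profile is normalized per stage position,
$I_N = 2I/I_{jT} - 1$ with $I_{jT}$ twice the profile mean, which removes
the extra absorption and refraction of the tilted views that the signal
model does not capture. Propagating the count noise through this
normalization gives the variance used for the fit weights
(`normalizedVariance()`):

$$ \sigma_N^2 \;=\; \frac{g\, I_{ji}}{I_{jT}^2}
   \;+\; \frac{g\, I_{ji}^2}{N_P\, I_{jT}^3}. $$

This is the published propagation formula, implemented verbatim. An exact
first-order propagation of $I_N = 2I/I_{jT} - 1$ would carry an additional
overall factor of about 4; since the factor is (nearly) common to all
residuals it rescales $\chi^2$ without moving its minimizer, so the fitted
parameters are unaffected. Consequence for users: the absolute $\chi^2$
values reported by `fitPixel()` are useful *relative* quality measures
(artifact and crossing-fiber detection via outliers) but should not be read
as $\chi^2$-distributed with the nominal degrees of freedom. Counts below
`weightFloor` (default 1) are clamped so zero-count samples keep a finite
weight.

## The ROFL fitter

`fitPixel()` implements Robust Orientation Fitting via Least Squares:

1. **Fourier direction.** The model contains only a DC term and the second
   harmonic in $\rho$, so a discrete harmonic projection of the *planar*
   profile (`extractModalities()`) recovers the starting direction
   $\varphi_0$ analytically — and, as side products, the transmittance and
   retardation modalities.
2. **Grid initialization.** $\chi^2$ is scanned over a 6 × 6 grid of
   $(\alpha, d)$ at $\varphi_0$ (`gridInit()`). Nodes sit at the centers of
   equal bins over $[-90°, 90°] \times (0, 1]$, i.e. $\alpha \in \{\pm 15°,
   \pm 45°, \pm 75°\}$, $d \in \{1, 3, \ldots, 11\}/12$, avoiding the
   degenerate edges. Because the model is a second harmonic, $\chi^2$ is
   quadratic in the per-view amplitude pair; precomputing weighted data
   moments turns the whole scan into a few matrix products.
3. **Unbounded Levenberg–Marquardt.** Starting from the best node, an
   unconstrained LM fit (`minpack.lm::nls.lm`, tolerances $10^{-10}$, at
   most 200 iterations) refines $(\varphi_u, \alpha_u, d)$. The model
   evaluation is invariant under the spherical symmetries, so no box
   constraints are needed — LM can wander freely without leaving the
   physically meaningful set.
4. **Symmetrization.** The result is folded back into the standard
   parameter space by `symmetrizeOrientation()`:
   $\varphi = \varphi_u \bmod \pi$, a matching sign-corrected fold for
   $\alpha$, and $d \mapsto |d|$. The fold leaves the model value — and
   hence $\chi^2$ — unchanged.

$d$ is deliberately *not* capped at 1: fitted $d > 1$ flags that the
single-fiber model does not describe the pixel (typically fiber crossings),
which is diagnostic information. If LM fails to improve on its
initialization the initialization is returned, flagged as not converged —
the fit never errors on valid data.

The model evaluation avoids all trigonometric inversions: with the tilted
unit vector components $(x, y, z)$,
$\cos^2\alpha_j = x^2 + y^2$, $\cos 2\varphi_j = (x^2 - y^2)/(x^2 + y^2)$
and $\sin 2\varphi_j = 2xy/(x^2 + y^2)$, all invariant under $v \to -v$, so
no half-sphere folding is needed in the hot loop. One pixel fits in roughly
2 ms; `fitImage()` maps the fit over a stack (optionally with forked
workers — the fit is deterministic, so results are identical for any worker
count) and masks background pixels by their planar transmittance.

## Validation harness

Because experimental tissue stacks are not distributable, correctness is
established by simulation:

* `runAccuracyStudy()` simulates noisy measurements on an
  $(\alpha, d)$ grid at fixed direction 45° — the worst case for the
  four-point tilting scheme, where the fiber azimuth bisects neighboring
  tilting directions — and reports the mean acute-angle error
  $\gamma = \arccos|v_{\mathrm{fit}} \cdot v_{\mathrm{truth}}|$ and the mean
  relative thickness error $\sigma_d = |d_{\mathrm{fit}} -
  d_{\mathrm{truth}}|/d_{\mathrm{truth}}$ per cell.
* `runUniformStudy()` samples orientations uniformly on the sphere
  (normalized Gaussian triples), whose inclination density follows the
  cosine law $p(\alpha) = \frac{\pi}{360}\cos\alpha$ per degree
  (`fitCosine()` recovers the factor $\pi/360 \approx 0.0087$). Comparing
  truth and fitted inclination histograms exposes systematic inclination
  biases; a sound fitter shows no depletion dip around $\alpha = 0$, a
  documented failure mode of earlier analytical (discrete Fourier
  transform over tilt positions) inversion methods. The `solver` hook takes
  any `function(series) -> PixelFit` so alternative inclination solvers can
  be benchmarked on identical data.
* `generatePhantom()` builds image stacks from rectangular regions with
  known parameters (plus a dimmer, retardation-free background), so the full
  image pipeline — stack I/O, masking, per-pixel fit, map I/O — can be
  checked for exact noise-free recovery and sensible noisy recovery.

The replicate counts used by the package's tests (300 per grid cell) and the
acceptance script (500; 2000 for the single hard configuration) are the
package's own choice: large enough that cell means have standard errors well
below the tolerances checked, small enough to run in minutes on one CPU.

### Known accuracy characteristics

At the standard signal level the fitter recovers flat, well-myelinated
fibers to about 1° mean orientation error; errors grow towards small $d$
(vanishing amplitude) and steep $\alpha$ (the tilt-induced signal
differences shrink), reaching tens of degrees only where the retardation
nearly vanishes. Thickness recovery degrades towards $\alpha = 90°$, where
$d$ is nearly unidentifiable — at $(\alpha = 90°, d = 0.9)$ the mean
relative error is about 42%. Averaged over $d \in [0.2, 0.9]$,
$\alpha \in [20°, 90°]$ the mean relative thickness error is about 20% under
this noise model. Note the internal tension: a published summary of ~5% for
that region is not attainable by *any* estimator at the noise level pinned
by the 42% figure, and the package reports the honest value.

## Numerical and design choices

* **Angles** are radians everywhere in memory; degrees appear only at I/O
  boundaries (CLI, files, printed output).
* **Weights are fixed at the measured data** before optimization (weighted
  least squares, not iteratively reweighted), matching the published
  estimator.
* **Optimizer tolerances** ($10^{-10}$) are far below the statistical noise
  floor; the fit has 3 parameters on 90 data points, so the extra iterations
  are cheap and noise-free recovery is exact to $10^{-6}$ or better.
* **Stack I/O** uses one directory per stack: a JSON metadata sidecar plus
  one multi-page 32-bit TIFF per stage position, values stored normalized by
  the recorded maximum count (the installed TIFF binding cannot write
  float-typed samples; 32-bit normalized storage is lossless for integer
  counts). Parameter maps are stored analogously with per-map affine ranges
  and an 8-bit mask.
* **Path-length correction** ($d_j = d/\cos\tau_j$ on tilted views) is
  available in the forward model but off by default; at $\tau = 5.51°$ it is
  a 0.5% effect.

## Limitations

* The single-fiber model cannot represent crossing or fanning fibers within
  a pixel; such pixels surface as $\chi^2$ outliers and $d > 1$, not as
  meaningful orientations.
* The phantom generator uses piecewise-constant regions and independent
  per-pixel noise; it does not model optical blur, dust, vignetting or
  inter-pixel correlations of real stacks.
* The noise model treats every count as independent negative binomial with a
  single global gain; real cameras can show structured noise.
* Tilting is modeled purely as a rotation of the fiber axis (plus the
  optional path-length term); tilt-dependent absorption or refraction
  effects are only absorbed by the per-view normalization, not modeled.
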