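Package: rofl
Title: Robust Orientation Fitting via Least Squares for 3D Polarized Light Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models, simulates and fits the birefringent light-intensity signals
    measured by 3D Polarized Light Imaging (3D-PLI) of unstained brain sections
    with a tiltable specimen stage. Implements the sinusoidal forward model of the
    rotation profiles, a calibrated negative-binomial photon-noise model, harmonic
    extraction of the standard modalities (transmittance, direction, retardation),
    and the ROFL weighted least-squares fitter that disentangles the 3D fiber
    orientation (direction and inclination angle) from the birefringence strength
    (relative section thickness) using oblique-view measurements. Includes a
    Monte-Carlo simulation harness for parameter-recovery accuracy surfaces and
    inclination-bias evaluation, a synthetic phantom generator, and TIFF/JSON
    stack and map input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    minpack.lm,
    parallel,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
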