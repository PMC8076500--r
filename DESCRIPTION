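Package: exotran
Title: Finite-Volume Simulation of Exosome Transport in the Tumor
    Microenvironment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Continuum modelling of exosome (extracellular vesicle)
    transport as a scalar advection-diffusion equation on Cartesian and
    axisymmetric finite-volume grids, one-way coupled to steady
    incompressible Stokes/laminar interstitial flow around cell
    obstacles. Includes selectable advective face-reconstruction schemes
    (first/second-order upwind, QUICK, minmod-limited MUSCL), an exact
    Gaussian-source-in-planar-shear verification benchmark with
    convergence-order studies, a stagnant-medium transwell diffusion
    scenario driven by measured per-cell release rates, and two-stage
    tumor-microenvironment scenarios with synthetic or image-segmented
    cell layouts. Writes VTK structured grids, CSV monitor series and
    JSON summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    EBImage,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
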