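Package: pxct
Title: Quantitative Densitometry for Ptychographic X-Ray Computed Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for quantitative analysis of ptychographic X-ray computed
    tomography (PXCT) phase volumes of silicified microfossils and similar
    mineralized specimens. Converts refractive-index decrement maps to electron
    and mass densities, segments material phases, removes partial-volume
    boundary voxels by morphological erosion, decomposes electron-density
    histograms into Gaussian components with air normalization, matches phase
    densities against mineral candidates, classifies carbonaceous matter by
    density, and estimates 3D resolution by Fourier shell correlation with the
    half-bit threshold. Includes a parallel-beam tomography toolbox (forward
    projection, phase-ramp removal, filtered back projection) and a synthetic
    phantom generator emulating kerogenous filaments, iron-oxide crystals and
    voids in a quartz matrix, so every stage of the pipeline can be validated
    against known ground truth without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
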