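Package: virionquant
Title: Quantifying Giant-Virus Replication from Soft X-Ray Micrographs,
    End-Point Dilution Titration and Thermogravimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the replication of giant DNA viruses inside
    amoebal host cells from water-window soft X-ray micrographs and classical
    virology assays.  Provides virion counting from cross-mark annotations
    with an explicit two-part error model (false positives scaled from
    non-infected controls plus a projection-geometry orientation loss),
    Beer-Lambert absorbance mapping with 2D-Gaussian illumination estimation
    and displaced-medium compensation, Poisson maximum-likelihood inference
    of infectious titre and burst size from end-point dilution titrations
    (TCID50 with profile-likelihood confidence intervals), and
    thermogravimetric residual-carbon arithmetic linking burst size and
    particle volumes to host-to-virus biomass-conversion intervals.  A
    synthetic phantom generator renders micrographs with known ground truth
    (analytic ray-ellipsoid projection, Gaussian illumination, Poisson
    photon noise) so the whole pipeline is testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
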