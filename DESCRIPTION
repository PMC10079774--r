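Package: sfdimodels
Title: Diffuse Reflectance Models for Spatial Frequency Domain Imaging
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analytical models of the spatially modulated diffuse
    reflectance of turbid media as measured by spatial frequency domain
    imaging (SFDI), together with the machinery needed to validate them:
    closed-form reflectance models derived under the partial-current and
    extrapolated boundary conditions alongside the widely used Cuccia
    model, pencil-beam diffusion Green's functions and their numerical
    zeroth-order Hankel transforms, a weighted-photon Monte Carlo
    simulator of steady-state transport in semi-infinite media with
    Henyey-Greenstein and two-term Henyey-Greenstein scattering, inverse
    extraction of absorption and reduced scattering coefficients from
    two-frequency reflectance, and a grid evaluation study that scores
    each model against the Monte Carlo ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
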