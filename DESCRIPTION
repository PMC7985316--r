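Package: rfaoptics
Title: Time-Domain Diffuse Optical Monitoring of Radiofrequency Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modelling for broadband time-domain diffuse
    optical spectroscopy (TD-DOS) of biological tissue undergoing
    radiofrequency thermal ablation. Includes a white Monte Carlo photon
    transport model for slab transmittance, radiative-transfer scaling and
    Beer-Lambert absorption, a diffusion-approximation reference solution,
    instrument-response-function convolution and Poisson counting noise,
    recovery of absorption and reduced scattering spectra from photon
    time-of-flight histograms, quantification of treatment signatures
    (Mie power-law scattering parameters, spline-based peak shifts,
    per-wavelength paired significance testing), and a synthetic heated-tissue
    generator emulating critical (70 C) and over- (105 C) treatment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
LinkingTo: Rcpp
Config/testthat/edition: 3
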