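Package: aavmp
Title: Mass Photometry Analysis of Adeno-Associated Virus Capsid Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for single-particle mass photometry of
    adeno-associated virus (AAV) preparations: linear ratiometric-contrast
    to molar-mass calibration from standards (thyroglobulin, empty AAV9),
    mass-histogram construction and Gaussian deconvolution into empty,
    partially filled, full and overfull capsid subpopulations, gate setting
    from mostly-empty/mostly-full reference samples, transgene (payload)
    mass estimation, and rough capsid-titer estimation from the binding
    count rate via a calibrated landing factor. Includes a seeded synthetic
    binding-event generator emulating Poisson landing statistics, instrument
    focus/operation modes, calibrant standards and crude-harvest
    backgrounds, so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    mclust,
    minpack.lm,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
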