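Package: flimcal
Title: Quantitative Calcium Imaging from Fluorescence Lifetime Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phasor-space calibration and quantification for fluorescence
    lifetime imaging (FLIM) calcium biosensors. Converts phase/modulation
    lifetimes to phasor coordinates, projects measurements onto the two-state
    mixing line between the calcium-free and calcium-saturated sensor states,
    corrects for the brightness ratio of the two states, fits the Hill binding
    model to calibration series, and converts lifetime images to absolute
    calcium-concentration maps. Also provides time-domain TCSPC decay modeling
    (a biexponential convolved with a Gaussian instrument response plus uniform
    background), chi-squared decay fitting, empirical-lifetime estimation,
    protein photophysics utilities (quantum yield, extinction coefficient,
    two-state intensity ratio), and seeded synthetic-data generators for every
    input the pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
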