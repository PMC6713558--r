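Package: gvsfit
Title: Dose-Response Model Comparison for Galvanic Vestibular Stimulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Compares linear, directly proportional, and saturating exponential
    dose-response models of ocular torsion and perceived visual tilt under
    galvanic vestibular stimulation. Models are fitted to published summary
    tables by constrained full-grid least squares over nonnegative parameter
    ranges, with variance explained used for nested model comparison. Includes
    the Zink et al. (1998) summary table as a packaged fixture, closed-form
    ordinary least-squares oracles for validating the grid search, a synthetic
    study generator for parameter-recovery simulation, and an end-to-end
    reanalysis pipeline with residual-sum-of-squares surface, fit overlay, and
    torsion-versus-tilt figures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
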