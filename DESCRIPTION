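Package: cottonwl
Title: Waterlogging Stress Response Functions for Early-Season Cotton
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the response of cotton growth and
    physiology to waterlogging duration. Implements the waterlogging
    stress response index (WSRI: a parameter's treatment mean divided by
    its 0-day control mean), least-squares fitting and selection of the
    three duration-response families used for early-season cotton
    (linear, quadratic and exponential decay), a packaged registry of 26
    published response curves, a soil-oxygen depletion and anoxia
    accounting model, prediction of the delay to first square, a
    synthetic-data generator emulating the 8-treatment by 5-replicate pot
    experiment, and a minimal daily-step growth simulator that applies
    the photosynthesis stress factor to a potential-growth accumulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
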