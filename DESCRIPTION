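Package: platecount
Title: High-Throughput Colorimetric Enumeration of Microbes from
    Plate-Reader Growth Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates viable microbial counts (CFU/mL) over five to seven
    orders of magnitude from 96-well microplate-reader optical-density
    time series. Extracts per-well growth kinetics (baseline, time to an
    absolute OD threshold, doubling time, tangent lag time), converts
    threshold-crossing delays across a ten-fold dilution ladder into
    relative survival, calibrates the linear range of the ladder, and
    anchors absolute counts with a single spread-plate reference.
    Includes limiting-dilution Poisson statistics for trace and
    single-cell wells, a treated-versus-control comparison for sublethal
    heat injury, a consumables/cost calculator for spread-plate versus
    microplate workflows, and a seeded synthetic plate-run simulator used
    as the ground-truth oracle throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
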