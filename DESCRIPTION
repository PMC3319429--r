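Package: loopfold
Title: Loop-Based Thermodynamic Prediction of RNA Secondary Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nearest-neighbor thermodynamic modelling of RNA secondary
    structure. Implements loop-based free-energy evaluation of
    sequence/structure pairs, Zuker-style minimum-free-energy folding with
    hard constraints, canonical-only (no lonely pair) and circular modes,
    the McCaskill partition function with base-pair probabilities, centroid
    and maximum-expected-accuracy structures, positional entropy and
    Boltzmann-weighted stochastic sampling, complete suboptimal enumeration
    within an energy band and Zuker-style per-pair suboptimals, scanning
    local folding with windowed pair probabilities and accessibilities,
    intermolecular duplex prediction, and standard benchmark statistics for
    comparing predicted against reference structures. Energy parameters are
    read from human-readable text files structured like the Turner 2004
    compilation; a complete default set is bundled.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
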