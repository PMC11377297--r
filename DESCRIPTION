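Package: ringpull
Title: Monte Carlo Simulation and Fitting of Protein Ring Rupture Under
    DNA Tether Pulling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates rupture-force distributions for a protein ring
    (cohesin) topologically entrapping one or two worm-like-chain DNA
    tethers pulled at constant velocity in an optical trap, and estimates
    the ring's disengagement parameters (zero-force opening rate k0 and
    mechanical displacement delta) from observed rupture-force samples by
    moment matching with a two-dimensional golden-section search,
    Monte-Carlo likelihood confidence intervals and bootstrap stability
    checks.  Also provides a stochastic bead-attachment model that infers
    the distribution of rings per bead from per-DNA occupancy tables, and
    seeded synthetic-data generators covering all experimental scenarios
    (single-population samples, crosslinked bimodal mixtures, two-DNA
    pulls, force-distance traces).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
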