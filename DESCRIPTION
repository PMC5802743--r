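Package: gmla
Title: Fast Spread-Source Localization on Complex Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Observer-based localization of the source of a spread
    (epidemic, rumor, malware) on a complex network. Provides a
    discrete-time Susceptible-Infected simulator with geometric per-edge
    delays, the Pinto-Thiran-Vetterli maximum-likelihood locator on
    limited information (PTVA-LI, arrival times only), and the Gradient
    Maximum Likelihood Algorithm (GMLA) which restricts scoring to the
    earliest-reporting observers and a gradient-selected suspect set.
    Includes the accuracy / rank / distance-error quality measures,
    observer-placement utilities, hub and noisy-observer diagnostics, and
    a seeded benchmark harness for quality-versus-size experiments,
    observer-count tuning and power-law fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
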