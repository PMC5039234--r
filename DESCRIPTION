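Package: knotweedbc
Title: Stage-Structured Delay Model for Biocontrol of Japanese Knotweed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analytical toolkit for a four-variable delay
    differential equation model of the biological control of Japanese
    knotweed (Fallopia japonica) by larvae of the sap-sucking psyllid
    Aphalara itadori. Integrates the stage-structured larva/adult/stem/
    rhizome system by the method of steps with distributed-delay survival
    factors carried as auxiliary cumulative-integral channels, and provides
    the accompanying linear analysis: insect-free growth/decay thresholds,
    the exponential-growth characteristic equation and its adults-per-stem
    ratio alpha(lambda), the critical handling time h_crit, coexistence
    equilibria, and real-root scans of the characteristic equation of the
    linearisation about the coexistence equilibrium.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
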