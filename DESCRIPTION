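Package: lampreysmr
Title: Sterile-Male-Release Suppression Analysis for Sea Lamprey Populations
Version: 0.1.0
Authors@R: person("Hammond Bay", "Analytics", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for evaluating sterile-male-release (SMR) suppression of
    invasive sea lamprey (Petromyzon marinus) populations. Implements the
    adult assessment chain (Lincoln-Petersen mark-recapture abundance from
    sterile-male recaptures, realized sterile:wild-male overflooding ratios,
    and viable-egg accounting before and after release), a Bayesian
    hierarchical negative-binomial model of age-1 larval recruitment with
    release-effort mortality fitted by adaptive Markov chain Monte Carlo with
    split-R-hat diagnostics, a seeded synthetic-data generator emulating the
    trapping, mating and overdispersed larval-survey processes, and a
    command-line interface for reproducible pipeline runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    coda,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
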