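Package: fibrilseq
Title: Statistical Modelling of Molecule-Type Sequences in Amyloid Proto-Fibrils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact and Monte Carlo machinery for a nearest-neighbour (Ising-chain)
    probability model of the order in which wildtype and variant transthyretin
    (TTR) molecules stack into amyloid proto-fibrils. Provides the Gibbs sequence
    distribution with enumeration and transfer-matrix normalisation, pattern
    statistics (perfectly alternating and k-error fibril fractions, enrichment
    over the random reference, parameter sweeps over the binding odds ratio and
    the variant:wildtype concentration ratio), conversions between the odds
    ratio, the nearest-neighbour coupling, the equilibrium constant and the
    standard Gibbs energy, and a seeded stochastic growth simulator with local
    and exact sampling modes, including a position-dependent field extension for
    tissue-templated growth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
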