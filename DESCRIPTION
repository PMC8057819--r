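Package: nutridom
Title: Nutrient Interactions and Dominance in Microbial Community Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative framework for studying how pairs of limiting
    nutrients shape the assembly of microbial enrichment communities. Implements
    a biomass-weighted null additive model that predicts community composition
    in a nutrient mixture from the communities assembled in each single
    nutrient, a replicate-pairing permutation test for nutrient interactions
    with classification into dominance, synergy and antagonism and a signed
    dominance index, a microbial consumer-resource model (MiCRM) simulator with
    two resource-specialist guilds for in-silico additivity and dominance
    experiments, growth-rate asymmetry statistics from optical-density time
    series, and synthetic data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
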