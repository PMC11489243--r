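Package: GolgiEnsemble
Title: Stochastic Simulation of the Cerebellar Golgi Cell Ensemble Conversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A seeded stochastic simulator of the cerebellar granular-layer
    Golgi cell ensemble conversion. Models the number of active parallel-fibre
    inputs to a Golgi cell (or a single apical dendrite) as a binomial count
    driven by the population activity density, and chains three random
    sampling-and-averaging stages: gap-junction charge equalisation across
    dendrite groups, somatic integration over dendrite triples, and glomerular
    sampling of Golgi cell firing rates. Includes parameter-sweep experiments
    quantifying how activity density and gap-junction group size govern the
    precision and accuracy (reproducibility) of the converted output, together
    with configuration handling, tidy CSV/JSON serialization and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'probability-model.R'
    'ensemble-sim.R'
    'experiments.R'
    'config-io.R'
    'plots.R'
    'utils.R'
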