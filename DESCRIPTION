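Package: cyanoflux
Title: Stoichiometric Analysis of Cyanobacterial Product Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constraint-based (flux-balance) analysis of phototrophic product
    synthesis in cyanobacteria. Provides an in-memory stoichiometric model class
    with elemental balance checking and isoenzyme handling, SBML and tabular
    model input/output, a linear-programming engine (flux-balance analysis,
    flux-variability analysis, parsimonious active-set estimation), a curated
    synthetic core phototrophic network with explicit photosystem, Q-cycle and
    ATP-synthase stoichiometry, a library of twelve heterologous product
    pathways with lower heating values, maximal-yield accounting
    (photons, NADPH, ATP, O2, Rubisco and CO2 per product), growth-versus-
    production trade-off scans, and in-silico transition experiments that
    classify per-reaction flux changes between a growth-only and a
    production-only phenotype.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
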