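Package: threadclamp
Title: Force-Clamp Analysis of DNA Threading Intercalation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of constant-force single-molecule DNA stretching
    experiments on slow threading intercalators. Fits single-exponential
    extension relaxations, extracts equilibrium occupancies through a
    worm-like-chain mixture model, fits the McGhee-von Hippel binding
    isotherm for per-force dissociation constants and binding site sizes,
    resolves Bell-model force dependences of the on, off and association
    rates, and derives the equilibrium elongation per bound ligand and the
    free-energy cost of the rate-limiting threading deformation. Includes a
    self-consistent synthetic force-clamp trace generator and an independent
    Gillespie lattice simulator so every stage of the pipeline can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'core-model.R'
    'bell.R'
    'io.R'
    'isotherm.R'
    'kinetics.R'
    'pipeline.R'
    'synthetic.R'
    'threadclamp-package.R'
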