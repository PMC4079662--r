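Package: xtalgp
Title: Gaussian Process Analysis of Protein Crystallization Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical analysis linking protein surface physico-chemistry and
    crystallization-cocktail composition to crystallization propensity.
    Computes 89 structure-derived protein features (surface residue coverage,
    category and neighbouring-pair fractions, side-chain entropy, hydropathy,
    polarity, isoelectric point, SASA, radius of gyration) and 61 solution
    features (species molarities, pH, ionic strength, Hofmeister coefficients,
    a depletion coefficient), fits automatic-relevance-determination squared
    exponential Gaussian process regression to transformed propensities with
    restart training, closed-form leave-one-out cross-validation, relevance
    reporting, and a linear baseline; fits sparse probit Gaussian process
    classification (informative-vector-machine style) to per-experiment
    outcomes for additive response curves and optimal-condition maps; performs
    hot-spot searches, sGRAVY-sSCE quadrant assignment, Kolmogorov-Smirnov
    enrichment tables, and crystal-contact profiling by symmetry expansion.
    Includes a synthetic screen generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
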