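Package: drugcascade
Title: Literature-Mined Disease Networks and Shortest Drug-Target
    Signalling Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for tracing how a drug can modulate a
    protein of interest through a disease protein-protein interaction
    network. Curates an abstract corpus, extracts gene/protein mentions by
    dictionary matching, weights disease association by document-level
    pointwise mutual information, induces a disease network from a
    reference interaction catalogue, extracts receptor-anchored drug
    interactomes and their shortest signal cascades, performs
    hypergeometric over-representation analysis against GMT collections,
    and implements the downstream validation arithmetic: 2^-ddCt relative
    expression, ELISA standard-curve quantification, and one-way ANOVA
    with Tukey HSD. Seeded synthetic-data generators emulate every input
    (abstract corpora, interaction catalogues with planted cascades,
    four-group qPCR and ELISA tables) so the whole pipeline runs and is
    validated without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
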