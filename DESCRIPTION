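Package: opbreed
Title: Genomic Evaluation and Optimum Contribution Selection for
    Open-Pollinated Progeny Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for genomics-based selective breeding of
    open-pollinated (OP) forest-tree families. Builds pedigree (A), genomic
    (G), dominance (D) and additive-by-dominance epistatic relationship
    matrices; verifies recorded pedigrees against genomic relatedness and
    builds threshold kinship networks; fits single-trait multi-site and
    multi-trait multi-site individual-tree mixed models by EM-REML with an
    average-information step for standard errors (ABLUP/GBLUP); back-solves
    SNP effects from genomic breeding values for GWAS-based SNP
    preselection; and performs optimum contribution selection under
    co-ancestry and correlated-trait constraints. A gene-dropping simulator
    of OP progeny tests with mixed sibships (selfs, full-sibs, half-sibs)
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    MASS,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
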