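Package: secretomeNet
Title: Quantitative Comparison and Enzyme-Class Co-Expression Networks for
    Fungal Secretomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative label-free quantitative secretomics of
    lignocellulose-degrading fungi. Implements replicate-based detection
    filtering, log2 plus Tukey-biweight normalization, signal-peptide
    consensus voting, CAZyme and peptidase category accounting with
    carbohydrate-esterase precedence, hierarchical clustering of substrate
    expression profiles, and a weighted enzyme-class co-expression network
    built by collapsing per-fungus protein correlation networks onto
    (possibly overlapping) enzyme-class sets, with node strengths, percent
    discretization and a binomial marginal-likelihood edge filter. Includes
    a synthetic-study generator with planted co-induced enzyme classes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Proteomics, Network, Clustering, Software
RoxygenNote: 7.3.3
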