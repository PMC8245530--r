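Package: trophicmode
Title: Gene-Content Prediction of Trophic Mode and Flow-Cytometric
    Bacterivory Assays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the trophic mode (phagotrophy,
    photosynthesis, prototrophy) of microbial eukaryotes from gene content,
    and for quantifying bacterivory from flow-cytometry feeding assays with
    fluorescently labelled bacteria.  The prediction arm clusters proteomes
    into gene families by all-vs-all similarity followed by Markov
    clustering, builds position-specific profile models, tests families for
    trait enrichment with a two-proportion test, summarises enriched
    families into weighted Gene Ontology category scores, selects predictive
    categories with the Boruta all-relevant algorithm, and calls
    capabilities with a probabilistic (Parzen) neural network; predictions
    are placed on an equal-area Mollweide map via a tetrahedral composition
    embedding.  The assay arm gates algal populations, establishes baseline
    green-fluorescence thresholds, computes the fed-cell percentage and its
    change over incubation, and applies the Shapiro-Wilk / F-test /
    one-tailed Student-or-Welch decision chain.  Both arms ship synthetic
    generators (proteome worlds with planted trait-linked families;
    cytometry event tables with ingestion dynamics and photobleaching
    background) used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    methods,
    ranger,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
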