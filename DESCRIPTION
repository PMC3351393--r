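Package: endoreprog
Title: Quantification of Duct-to-Endocrine Transcriptome Reprogramming
    from Probe-Level Expression Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies how far a transcription-factor-driven
    reprogramming of pancreatic duct cells towards the islet endocrine
    state has progressed, starting from probe-level oligonucleotide
    array intensities.  Implements a multiplicative model-based
    expression index with mismatch (PM-MM) correction and iterative
    outlier exclusion, fold-change confidence intervals whose lower
    bound (LCB) is the differential-expression measure, a compound
    two-timepoint regulated-transcript rule with a time-course rescue
    clause, duct-to-endocrine reprogramming-completeness scores
    (path-completion fraction, overlap fraction, conserved marker-panel
    signal), tissue-tropism classification of regulated genes against a
    multi-tissue expression atlas with correlation/centroid
    hierarchical clustering, and hypergeometric gene-set
    over-representation.  A synthetic probe-level data generator with
    known ground truth makes every stage testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
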