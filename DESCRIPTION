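Package: xcal
Title: Cross-Build E-Value Calibration for Profile HMM Domain Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calibrates a protein domain-model library so that E-values from a
    fast multihit-local profile-HMM search and a slow glocal (global on the
    model, local on the sequence) search become comparable through
    false-positive ranks on a common negative set of consensus sequences.
    Per model, the more sensitive build is selected by normalized partial-AUC
    differences over a grid of false-positive counts, and a three-stage
    annotation workflow (local scan, glocal full-domain re-alignment,
    FPR assignment) annotates query sequences with standardized
    false-positive rates, an analytical speed model and a concordance screen
    for flagging discrepant annotations. Includes a deterministic synthetic
    domain-library and query-set generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    Biostrings
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
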