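Package: poolplan
Title: Planning Cost-Optimal Pooled NGS Experiments for Rare-Mutation
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Plans pooled next-generation-sequencing experiments for the
    detection of rare mutations in patient cohorts. Allocates patients into
    main and replica (control) pools under four deterministic algorithms
    (NoReplica, OptReplica, Transposition, DiagWalks), evaluates each design
    by its total cost (NGS pool sequencing plus Sanger confirmation of
    ambiguous assignments), its waiting time before sequencing of the first
    complete pool unit can start, and its decodability, sweeps candidate
    pool sizes, and recommends the cost-optimal configuration. Includes an
    idealized pool-readout simulator that verifies, by signature-intersection
    decoding, that the budgeted number of Sanger tests covers every
    ambiguity a design can produce.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
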