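Package: revsig
Title: Signature-Reversal Drug Repurposing from Gene Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained drug-repurposing pipeline built on the
    transcriptomic reversal hypothesis: a compound whose perturbation
    profile negates a disease expression signature is a candidate
    therapy. From a two-group (normal vs disease) log2 expression
    matrix the package computes moderated or Welch differential
    expression, extracts top-N up- and down-regulated tag lists,
    scores every perturbagen in a rank-profile compendium with a
    bidirectional Kolmogorov-Smirnov connectivity score normalized to
    a signed percentile tau in [-100, 100], ranks reversal candidates,
    runs pre-ranked gene-set enrichment, and summarizes validation
    annotations. A synthetic-data generator with planted ground truth
    emulates the public expression series and perturbagen compendia
    the method is normally applied to, so every stage is testable
    offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    fgsea
Config/testthat/edition: 3
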