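Package: graftDE
Title: Consensus Pairwise Differential Expression for Liver Graft Transcriptomes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for acute-phase liver graft transcriptomes
    contrasting recipients with and without post-transplant tumour recurrence.
    Implements RPKM quantification from gene-level read counts, an all-pairs
    consensus differential-expression procedure (every recurrence sample
    compared against every non-recurrence sample, directionally inconsistent
    genes removed, log-scale averaged fold changes), hypergeometric gene-set
    over-representation with Benjamini-Hochberg adjustment, 2^-ddCt qPCR
    relative quantification against a healthy-donor calibrator cohort, and
    Pearson correlation panels of candidate genes against interaction
    neighbours. Ships a negative-binomial count simulator with planted fold
    changes so the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
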