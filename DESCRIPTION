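Package: rarecode
Title: Codon Usage Bias and RNA-Binding Protein Motif Convergence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the convergence of synonymous codon usage and
    RNA-binding protein (RBP) regulation on mRNAs. Implements the codon
    adaptation index (CAI) from genome codon-usage tables (Kazusa format),
    position weight matrix (PWM) motif scanning of the 3' quartile of coding
    sequences plus 3'UTRs with exact score-distribution p-values, synonymous
    codon recoding (optimization, de-optimization, and motif-preserving
    recoding), cell-type expression enrichment calling from FPKM/TPM matrices,
    CAI-binned binding-site regressions and a candidate filter cascade, and
    qRT-PCR / mRNA-decay quantification. A seeded synthetic-data module
    generates inputs with planted structure so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
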