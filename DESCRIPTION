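Package: tagDGE
Title: Tag-Based Digital Gene Expression Profiling with an Exact Test for
    Count Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for SAGE-style digital gene expression (DGE) profiling
    from NlaIII/MmeI 21-nt sequence tags: construction of a virtual
    CATG+17-nt tag reference with one-mismatch lookup, raw-library cleaning
    (adaptor-only, N-containing and singleton tag removal), tag-to-gene
    mapping and per-gene quantification in transcripts per million clean
    tags (TPM), differential expression between two tag libraries with the
    Audic-Claverie exact conditional test under Benjamini-Hochberg false
    discovery rate control, hypergeometric term enrichment of differentially
    expressed gene sets, and qPCR (2^-ddCt) and knockdown (percent of
    control) validation statistics. A seeded protocol simulator generates
    reference transcriptomes and raw tag libraries with full ground truth so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
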