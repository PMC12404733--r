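Package: wobbleseq
Title: Wobble-Inosine Stoichiometry and Differential tRNA Abundance from tRNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies A34-to-I34 wobble-inosine editing of ANN-decoding tRNAs
    from tRNA-seq reads by exploiting the reverse-transcriptase signature of
    inosine (read as G), assigns reads to isodecoders with modification-aware
    scoring, estimates per-isodecoder and per-anticodon I34 stoichiometry with
    Wilson confidence intervals, tests differential tRNA abundance under a
    negative-binomial model with median-of-ratios normalization and
    Benjamini-Hochberg correction, measures the coupling between I34 loss and
    tRNA destabilization by rank correlation with permutation inference, and
    tests gene sets for enrichment of ADAT-dependent (C-ending) codons. A
    fully ground-truthed synthetic-data generator emulates tRNA-seq libraries
    for validation, and in vitro deamination assays are summarized from base
    counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
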