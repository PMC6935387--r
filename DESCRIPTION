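Package: spliceprops
Title: Characterization of Mis-Spliced Events Against Matched Control Constructs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream characterization of differential-splicing events from
    rMATS-style tables. Builds matched internal (within-gene) and external
    (highly expressed gene) exon-intron control constructs, trains positional
    log-odds splice-site models from a genome and GTF annotation, predicts
    branch points and branch-point to 3' splice-site distances, computes
    length/GC feature vectors, classifies the coding consequence of retained
    introns (in-frame premature stops and frameshifts), and statistically
    compares event groups against the control sets, including a discriminative
    k-mer motif enrichment test. Ships a fully self-contained synthetic data
    generator (genome FASTA, GTF, rMATS-style event tables, expression table,
    ground-truth manifest) so the whole pipeline can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
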