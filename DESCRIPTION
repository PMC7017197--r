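Package: circActivity
Title: Circular RNA Detection, ceRNA Network Inference and Translation
    Screening for Neuronal Depolarization Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects circular RNAs from split-read alignments by the
    back-splice (reverse-order segment) rule, quantifies them as
    back-splice junction reads per million mapped reads, performs
    two-group differential expression with an exact conditional binomial
    test, predicts canonical miRNA seed sites with a simplified context
    score, assembles a direction-constrained circRNA-miRNA-mRNA
    competing-endogenous-RNA network ranked by eleven topological
    centrality methods, screens ribosome-footprint reads against a 36-nt
    back-splice junction index, and predicts rolling-circle open reading
    frames on circular templates. Ships a synthetic-data generator with
    planted, machine-readable ground truth so the whole pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
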