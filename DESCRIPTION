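Package: nmdkit
Title: Discovery and Prioritisation of Splicing Events Coupled to
    Nonsense-Mediated Decay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates custom transcriptomes against a reference, predicts
    open reading frames on assembled transcripts by projecting annotated
    start codons, calls nonsense-mediated decay (NMD) sensitivity by the
    50-nt rule, extracts the cassette-exon, alternative-donor/acceptor and
    retained-intron events responsible for NMD sensitivity, prioritises
    events by splicing-expression correlation, monotonic-trend and
    enrichment statistics and by intronic-flank conservation, and simulates
    an ODE model of coordinated NMD-dependent and NMD-independent gene
    downregulation. Ships a deterministic synthetic-fixture generator so
    the whole workflow is testable on toy genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    deSolve,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
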