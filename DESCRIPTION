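Package: camlnc
Title: Identification and Diel Analysis of Leaf Long Noncoding RNAs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide identification and characterization of
    leaf long noncoding RNAs (lncRNAs) in crassulacean acid metabolism (CAM)
    plants. Assigns class codes to assembled transcripts against a reference
    annotation, applies a five-criterion lncRNA filter (length, coding
    potential, protein domains, strand, expression) with a per-step audit
    funnel, classifies lncRNAs into intergenic (lincRNA) and natural
    antisense (lncNAT) biotypes, summarizes genomic features, scores tissue
    specificity by the Tau index and Shannon entropy, builds Pearson
    co-expression networks over diel time courses, constructs competing
    endogenous RNA (ceRNA) pairs from shared miRNA binding, and detects
    diel-cycling transcripts by correlation to phase-shifted model waveforms
    with a permutation test. A synthetic-data generator with a ground-truth
    manifest makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Network, Annotation
RoxygenNote: 7.3.3
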