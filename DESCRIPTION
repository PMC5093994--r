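Package: rgascan
Title: Genome-Wide Prediction and Classification of Plant Resistance Gene Analogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies resistance gene analogs (RGAs) in plant proteomes by
    integrating protein domain and motif evidence (NB-ARC, TIR, coiled-coil,
    LRR, LysM, kinase, transmembrane) from the standard output formats of
    InterProScan, pfam_scan, Phobius and coiled-coil scanners, applying an
    initial BLASTP similarity prefilter against a curated resistance-protein
    reference set, and classifying each protein through a domain-architecture
    decision tree into NBS-encoding subclasses (CNL, TNL, CN, TN, NL, NBS, TX,
    OTHER) and membrane-associated families (RLP, RLK, TM-CC). Includes a
    built-in sliding-window heptad scorer for coiled-coil detection, a
    deterministic chunked pipeline with per-chromosome distribution summaries
    from GFF3/GTF annotation, and a synthetic proteome generator with planted
    domain architectures for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
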