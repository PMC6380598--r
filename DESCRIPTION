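Package: annoforge
Title: Headless Genome Annotation Curation Engine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable genome-annotation editing engine: promotion of
    aligned or predicted evidence into editable gene models with automatic
    longest-ORF calculation, splice-aware structural edits (merge, split,
    boundary dragging and snapping to donor/acceptor dinucleotides),
    reading-frame-aware isoform grouping, application of sequence
    alterations (assembly corrections and natural variants) with coordinate
    remapping and re-projection of annotations, and a fully attributed,
    revertible per-feature edit history with undo/redo.  Models are read
    and written as FASTA, GFF3, BED, VCF, GenBank flatfile and a compact
    JSON snippet format; a command-line interface drives whole curation
    sessions from edit scripts.  A deterministic synthetic-genome generator
    with a planted-truth manifest supports end-to-end testing without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
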