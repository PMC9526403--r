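Package: mitocistron
Title: Fungal Mitogenome Characterization and Polycistronic Transcript Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing circular fungal mitochondrial genomes and
    for inferring polycistronic transcription units from short-read transcript
    evidence. Computes nucleotide composition and strand skew statistics,
    catalogues intergenic, overlapping and intronic regions under circular
    coordinate arithmetic, validates group I intron splice boundaries and scans
    intron open reading frames, classifies transcript contigs and split reads
    (splicing, intron-containing, wrap-around, polyadenylated), and merges
    contig evidence across gene junctions -- including tRNA punctuation
    bridging -- into polycistronic units with a transcription-start candidate
    region. A synthetic mitogenome and RNA-processing simulator with ground
    truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    Rsamtools,
    GenomicAlignments
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
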