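Package: polyrearrange
Title: Chromosomal Rearrangements and Subgenome Dynamics in Allopolyploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the subgenome structure of allopolyploid
    (e.g. allotetraploid) genomes from standard annotation and alignment files.
    Chains homologous gene pairs into orientation-signed collinear blocks,
    calls translocations, inversions and segmental duplications from breaks in
    homoeologous collinearity combined with diploid-relative synteny, genotypes
    a large inversion across a resequencing panel by counting insert-size-gated
    discordant read pairs at its breakpoints, quantifies subgenome-biased
    transposable-element family dynamics, and checks genetic-versus-physical
    map concordance by marker flank placement. Includes a seeded synthetic
    allotetraploid generator with planted rearrangements and simulated
    paired-end alignments for end-to-end validation against known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
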