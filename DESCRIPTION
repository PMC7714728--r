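Package: bhbscan
Title: Discovery of Archaeal Splicing-Endonuclease Substrates from
    Circularized-Intron Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding substrates of the archaeal tRNA splicing
    endonuclease from circRNA-seq style data. Calls splice-site pairs from
    split-read alignments, classifies linear versus circularized introns,
    applies replicate-coverage filtering and proximity merging, searches the
    glued exon-flank context of each candidate for the strict
    bulge-helix-bulge (hBHBh') structural motif with a nearest-neighbor
    stacking stability score, and simulates endonucleolytic cleavage and
    ligation (ligated exons plus circularized intron). Includes a synthetic
    genome and read-set generator with planted BHB-flanked introns and exact
    ground truth, so the whole pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
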