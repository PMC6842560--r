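Package: genefamkit
Title: Genome-Wide Gene Family Identification and Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for genome-wide characterization of a
    transcription-factor gene family from a proteome and its annotation:
    profile-based domain identification with a local-alignment cross-check,
    neighbor-joining classification into subfamilies against labeled
    references, chromosomal renaming and 200-kb gene-cluster detection,
    reciprocal-best-hit orthology, tandem/segmental duplication calling under
    a 65/65 coverage-similarity rule, exon-intron statistics, deterministic
    protein motif scanning, physicochemical property calculation, RPKM and
    2^-ddCt expression quantification, and the family-table summary
    statistics that describe the family census. A synthetic-data generator
    with a recorded ground-truth manifest makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
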