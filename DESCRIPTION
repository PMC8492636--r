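Package: mirmarker
Title: miRNA-Derived and Semi-Random ISSR Functional Markers with
    Bulked-Sample Candidate Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing miRNA-derived and semi-random anchored
    ISSR (inter-simple sequence repeat) molecular markers from annotated
    mature miRNA and transcript sequences, predicting marker bands by
    in-silico PCR, scoring binary band matrices, quantifying polymorphism
    information content (PIC), clustering genotypes with Jaccard similarity
    and UPGMA, and selecting trait-linked candidate markers by bulked-sample
    contrast between phenotypic extremes. Includes a deterministic synthetic
    genotype-panel generator with planted microsatellite tracts, miRNA
    primer sites, and bulk-differential presence/absence loci for end-to-end
    validation of the marker pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
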