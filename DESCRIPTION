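Package: latchkit
Title: Beta-Bulge-Loop Latch Analysis for Reverse Gyrase Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the "latch" element of reverse gyrases and
    related beta-hairpin/beta-bulge-loop motifs. Detects backbone hydrogen
    bonds with the Kabsch-Sander electrostatic model, classifies the loop
    capping a two-stranded antiparallel beta-sheet as a beta-turn or a
    type-1/type-2 beta-bulge loop, performs Kabsch superposition with
    outlier rejection and displacement probes, enumerates heavy-atom
    contacts between regions, and computes latch-region sequence statistics
    (net charge at pH 7, hydrophobicity, length clusters, Smith-Waterman
    identity/similarity). Includes a synthetic-data generator that builds
    ideal beta-hairpins with known hydrogen-bond blueprints and sequence
    sets with planted length and charge composition, so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
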