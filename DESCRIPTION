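Package: saphire
Title: Structure-Aware Function-Potential Scoring of Post-Translational
    Modification Hotspots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates experimentally observed post-translational
    modification (PTM) sites onto protein-family alignment columns
    (modified alignment positions, MAPs), extracts six sequence and
    structure features per MAP (PTM count, solvent accessible surface
    area, residue conservation, protein-interface residence, neighbor
    count and neighbor known-function count), scores each MAP's function
    potential with a small tanh neural network, and provides the
    downstream analyses: hotspot calling against a source-count-derived
    threshold, enrichment versus random chance, PTM-type coincidence
    networks, and clinical missense-variant coincidence. Includes a
    seeded synthetic-data generator for every input format so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
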