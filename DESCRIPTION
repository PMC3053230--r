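Package: ringscape
Title: RING-Finger Zinc-Ligand Assignment, Interface Modelling and
    Transgenic-Rescue Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constraint-based detection and zinc-ligand assignment of
    RING-finger motifs (C4C4 and C3HC4 spacing models), pairwise divergence
    statistics, template ranking and CA-level rigid threading of structural
    models with distance-based interface-residue calling and zinc-site
    geometry validation, and quantification of transgenic-rescue brood data
    (line summaries, rescue fractions, cysteine-compensation logic).
    Includes seeded generators for synthetic motif-bearing sequences, toy
    zinc-site structures with a partner chain, and brood-count datasets with
    known ground truth, so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
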