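Package: bbscargo
Title: Membrane-Plane Placement, Tether Reach and Helix-8 Motif Analysis
    for BBSome-GPCR Cargo Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Geometric and sequence analyses of how the BBSome, the
    octameric coat complex that ferries G protein-coupled receptors out of
    cilia, can engage cargo whose amphipathic helix 8 normally lies in the
    inner membrane leaflet. Places a membrane plane on a complex from an
    amphipathic GTPase anchor helix, searches anchored orientations for
    the minimum cargo-site/membrane distance, converts tether residue
    counts into reach bounds under extended and helical models, scans
    GPCR helix-8 windows and PH-domain loops for BBSome-binding and
    PIP-binding motifs, quantifies domain rotations between
    conformations, and assesses steric occlusion of lipid-binding sites
    by template superposition and clash counting. Includes synthetic
    generators (ideal helices, planted membrane complexes, motif cohorts,
    clash fixtures) so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    seqinr,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
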