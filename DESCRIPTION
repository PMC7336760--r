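Package: cysloop
Title: Structural Interpretation of Missense Variants in Cys-Loop Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for placing protein-level missense variants of pentameric
    ligand-gated ion channels (Cys-loop receptors) into structural context.
    Provides cross-paralog residue-equivalence mapping by pairwise sequence
    alignment, M2 prime-position numbering anchored at the conserved 9'
    activation-gate leucine, per-helix disease-variant enrichment statistics
    for the four transmembrane helices, and channel-pore geometry profiling
    of pentameric structures (maximal inscribed-sphere radii along the pore
    axis, gate detection, chloride-passability classification). Includes
    synthetic-data generators with analytically known ground truth for
    validating every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
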