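Package: structaln
Title: Structure-Annotated Multiple Sequence Alignments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Annotates multiple sequence alignments with per-residue and
    per-column structural features computed from accompanying PDB
    coordinate files: secondary structure by backbone hydrogen-bond
    energy patterns, relative solvent accessibility and burial, mainchain
    phi sign, sidechain-to-mainchain hydrogen bonds, residue depth,
    inter-residue contacts, chain and ligand interfaces, gap-aware
    normalized Shannon entropy, secondary-structure consensus, percentage
    sequence identity, and per-column C-alpha RMSD after iterative
    variance-weighted multi-structure superposition. Results are stored
    in a versioned XML annotation document and rendered as a
    self-contained formatted HTML alignment. Includes deterministic
    synthetic-geometry generators (ideal helices, sheets, toy complexes)
    so the whole pipeline is testable without external data, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
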