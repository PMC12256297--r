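Package: hpslab
Title: Coarse-Grained Slab Simulations of Biomolecular Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: One-bead-per-residue molecular dynamics of intrinsically
    disordered protein (and single-stranded RNA) phase separation in
    periodic slab geometry, using a hydropathy-scale (HPS) force field
    with Ashbaugh-Hatch short-range and Debye-Hueckel electrostatic
    terms. Includes topology building from sequence, grid replication
    and box-compression protocols, Langevin dynamics with cell-list
    neighbour search, radius-threshold inter-chain contact analysis
    (per-residue profiles, contact networks, make/break transience,
    protein-RNA contact matrices), z-density profiles and coexistence
    phase diagrams, and a combinatorial mutation screen ranked by mean
    HPS interaction energy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
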