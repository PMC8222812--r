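Package: mdenm
Title: Molecular Dynamics with Excited Normal Modes for Ion-Channel Gating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Normal-mode-driven conformational exploration and geometric
    gating analysis for tetrameric potassium channels of the KirBac family.
    Computes low-frequency elastic-network normal modes, selects the modes
    that open or close the channel, runs replica Langevin dynamics with
    periodic kinetic-energy excitations along mode combinations (MDeNM),
    clusters the resulting structures on the channel region and relaxes
    representatives, and classifies every conformation into a five-state
    gating taxonomy from diametric inter-chain constriction distances.
    Also provides helix kink angles, cytoplasmic-domain rotation angles,
    per-residue ensemble RMSD, a simplified pore-radius profile, and a
    synthetic tetramer generator with ground-truth gating labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Matrix,
    jsonlite,
    yaml,
    methods,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
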