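Package: ionpairdyn
Title: Ion-Pair Lifetimes, Water Reorientation and Mean-Force Profiles
    from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trajectory analysis for salt-bridge and ion-pairing studies in
    aqueous molecular dynamics simulations. Reads extended-XYZ, GRO and
    xvg-style time-series files with orthorhombic periodic boxes, computes
    vector-reorientation autocorrelation functions with exponential
    time-constant fits, intermittent aggregate lifetimes under a distance
    criterion with ensemble-average correction, radial distribution
    functions with coordination numbers and first-shell occupancies,
    regional density ratios, and mean-force profiles along a forced
    (umbrella-pulling) dissociation coordinate, including comparison with
    the screened-Coulomb reference. A seeded synthetic-data module
    (rotational-diffusion rotor ensembles, two-state Markov bond kinetics,
    ideal-gas and shell-structured fluids, an overdamped Langevin pulling
    simulator) provides ground-truth inputs so every stage is testable
    without a molecular dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
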