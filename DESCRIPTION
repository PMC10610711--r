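Package: sorbtrack
Title: Analysis of Penetrant Sorption and Transport in Molecular Dynamics
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing water (or other penetrant) sorption in
    polymer-matrix molecular dynamics trajectories under orthorhombic periodic
    boundaries. Computes multi-origin mean-squared displacement and Einstein
    self-diffusion coefficients with automatic detection of the Fickian
    (log-log slope ~ 1) regime, detects hydrogen bonds by geometric
    distance/angle criteria with water-water / polymer-polymer / polymer-water
    class decomposition, partitions water molecules into single-linkage
    distance clusters with mass-weighted radii of gyration, and maps
    time-averaged density projections. Includes seeded synthetic-trajectory
    generators (Brownian, ballistic, confined walkers; planted cluster and
    hydrogen-bond scenes) providing exact ground truth for every analysis
    stage, plus a config-driven pipeline runner. Reads and writes multi-frame
    XYZ, multi-model PDB and GRO trajectories with plain-text topology
    sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
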