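Package: nanolink
Title: Topology and Viscoelasticity of Limited-Valence Nanostar Gels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for physical gels assembled from
    valence-3 DNA nanostars. Provides a rigid-body Langevin dynamics engine
    for patchy Y-shaped particles with Morse sticky patches, readers and
    writers for LAMMPS dump/data and XYZ trajectories, bonded-network graph
    construction, a minimum-loop census with Gauss linking-number analysis
    (catenation census, linking valence, link-network percolation),
    structural observables (random-insertion mesh size, branch-path and
    fractal statistics), microrheology via the generalized Stokes-Einstein
    relation and Green-Kubo stress autocorrelation, two-channel image
    colocalization, and seeded synthetic fixtures with known ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png,
    tiff
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
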