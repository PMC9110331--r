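Package: aquaclust
Title: Hierarchical Cage-Cluster Analysis of Hydrogen-Bond Networks in Water
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and characterizes three-dimensional cage-like water
    clusters in molecular configurations of liquid water. From oxygen and
    hydrogen coordinates in a periodic orthorhombic box, the package builds
    the geometric hydrogen-bond graph, enumerates shortest-path rings,
    assembles closed cage fragments, groups fragments into water clusters by
    Louvain community detection, and computes cluster statistics: alpha-shape
    volume and surface area, maximum diameter, size and morphology scaling
    fits, SPC/E interaction energies, local structure index, probe-sphere
    local density, radial distribution functions, and frame-to-frame cluster
    transformation dynamics. Synthetic structure generators (theta cages,
    hexagonal-ice lattices, random packings, ideal solids, power-law size
    samples) provide fixtures with known topology for validation. Readers and
    writers for XYZ, GRO and LAMMPS dump coordinate files are included, plus
    a small command-line driver.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
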