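Package: vesimc
Title: Dynamically Triangulated Monte-Carlo Simulation of Vesicles with
    Curved Active Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained simulation of a closed lipid-bilayer vesicle
    carrying mobile curved membrane-protein complexes (CMCs) that may exert
    active protrusive forces.  The membrane is a dynamically triangulated
    surface evolved by Metropolis Monte-Carlo vertex moves and bond flips
    under a discretized Helfrich bending energy, nearest-neighbour
    protein-protein binding, substrate adhesion, and an active work term
    with optional Vicsek-like force alignment and force inhibition between
    protein species.  Includes shape and cluster statistics (gyration
    tensor, cluster sizes, boundary perimeter, segregation factor), a phase
    classifier, closed-form force-balance theory for the tube transition,
    deterministic analytic fixtures, tape-style configuration parsing and
    VTU/PLY/CSV input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
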