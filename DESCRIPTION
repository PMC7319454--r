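Package: sitegeom
Title: Metal Coordination Geometry and Water Placement in Protein-Ligand Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale geometric analysis of protein-ligand binding sites from
    PDB files. Assigns and scores ideal coordination geometries for metal ions by
    optimal superposition of the observed coordination sphere onto a built-in
    library of reference polyhedra (distance RMSD, free coordination sites and a
    steric overlap penalty combined into a single score), places water molecules
    at unsaturated hydrogen-bond functions via ideal interaction directions, a
    self-assembling mean-shift clustering and local position optimization, and
    aggregates coordination-geometry frequencies and metal-partner distance
    distributions over structure sets. Includes a synthetic-structure generator
    with known ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
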