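Package: nlalchemy
Title: Alchemical Free Energy Calculations by Neighbor-List Manipulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale alchemical free energy engine built around a single
    idea: any cutoff-based potential sees the world only through its neighbor
    list, so atoms can be decoupled from their environment by masking them out
    of the list or by adding a lambda-dependent offset to selected pair
    distances (a linear shift or the norm of a 4D vector), without touching
    the potential itself. The package provides periodic particle systems,
    neighbor-list construction with four distance-shifting schemes, a smoothly
    switched short-range toy pair potential standing in for a machine-learned
    potential, flat-bottom restraints, BAOAB Langevin dynamics, BAR and MBAR
    free energy estimators with overlap pathology diagnostics, and protocols
    for absolute solvation free energies, a dual-topology relative
    transformation analog, and thermodynamic cycle-closure validation.
    Seeded fixture generators make every computation reproducible offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
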