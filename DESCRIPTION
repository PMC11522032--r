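Package: fibrilmd
Title: Coarse-Grained Steered Molecular Dynamics of Cross-Linked Collagen
    Fibrils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds bead-spring models of collagen fibrils with the
    D-periodic staggered geometry, inserts enzymatic and advanced-glycation
    end-product (AGE) cross-links, and runs displacement-controlled tensile
    tests with breakable trilinear bond potentials, harmonic bending and
    soft-core Lennard-Jones packing interactions. Includes energy
    minimization, Langevin dynamics with rigid end clamps, bond-rupture
    bookkeeping, and analysis of stress-strain curves, per-bond-type force
    histories, cross-link failure fractions and intra-fibrillar sliding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    ggplot2
Config/testthat/edition: 3
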