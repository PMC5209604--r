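Package: pseudem
Title: Pseudoatom Coarse-Graining of Cryo-EM Density Maps with
    Approximation-Error Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Represents 3D electron-microscopy density maps as weighted sums
    of fixed-width isotropic Gaussian functions (pseudoatoms), grown, pruned
    and refined until a user-set approximation error is met. The pseudoatom
    centers drive downstream analyses: elastic-network normal-mode analysis,
    mode-based deformation and animation, elastic 3D-to-3D fitting with a
    low-dimensional distance-space embedding, and map denoising by
    approximate-then-render. Includes MRC2014 map I/O, PDB pseudoatom model
    I/O, and a synthetic phantom generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
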