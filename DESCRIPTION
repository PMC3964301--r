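Package: gopull
Title: Coarse-Grained Steered Molecular Dynamics of Beta-Rich Protein Modules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds Calpha Go-like models of beta-rich protein domains from
    all-atom structures (native contacts with a 13/18/4 modified Lennard-Jones
    potential, native hydrogen-bond terms, harmonic angles and torsions),
    stretches them at constant velocity under Langevin dynamics with holonomic
    bond constraints and a moving harmonic spring, and characterizes the
    resulting maximum-unfolding-force distributions (Gaussian/bimodal fits,
    averaged force-extension curves, extension fractions) and qualitative
    unfolding scenarios. Includes deterministic generators of idealized
    beta-hairpin and beta-sandwich geometries so that the whole pipeline runs
    without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    mclust,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
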