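Package: crowdbd
Title: Brownian Dynamics of Crowded Cytoplasm Models with Mean-Field
    Hydrodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Coarse-grained Brownian dynamics of concentrated protein
    solutions such as the bacterial cytoplasm. Proteins are flexible
    clusters of one to five spheres built by k-means coarse-graining of
    alpha-carbon coordinates; spheres interact through harmonic stretching,
    bending and inter-protein repulsion, and hydrodynamic interactions are
    treated by a mean-field rescaling of each sphere's dilute-limit
    diffusion coefficient by the Tokuyama function of its local volume
    fraction. Includes an Ermak-McCammon propagator with periodic
    boundaries, builders for packed simulation boxes from composition
    tables or synthetic fixtures, and an analysis suite for multi-origin
    mean-squared displacement, block-averaged diffusion coefficients,
    anomalous-diffusion exponents and displacement autocorrelation
    diagnostics of fractional Brownian motion.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
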