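Package: embotrack
Title: Embolic Particle Transport in a Synthetic Circle-of-Willis Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of embolic particle transport in the cerebral
    arterial circulation. Generates an idealized three-inlet circle-of-Willis
    tube network, solves steady blood flow on it as a Hagen-Poiseuille
    resistance network with analytic in-tube velocity profiles, tracks
    spherical emboli through the reconstructed field with a
    Basset-Boussinesq-Oseen force balance (Schiller-Naumann drag, buoyancy,
    pressure-gradient and virtual-mass forces) and a restitution-based wall
    collision model, and computes the outcome statistics of interest for
    embolic stroke: exit-branch distributions, travel-speed and residence-time
    histograms, and particle path tortuosity. Includes fixed-mass-flow
    boundary conditions and anatomical variant networks with missing
    communicating arteries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
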