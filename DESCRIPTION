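Package: twlc
Title: Twistable Worm-Like Chain Models of DNA Under Force and Torque
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Equilibrium statistical mechanics of a single DNA molecule under
    applied force and torque.  Implements the discretized twistable
    worm-like-chain energy, DNA topology (twist, Gauss and Fuller writhe,
    linking number, superhelical density), Metropolis Monte Carlo sampling of
    supercoiled conformations, and the Wigner D-function transfer-matrix
    partition function with four coexisting structural states of the double
    helix (B-, L-, P- and S-DNA).  Produces force-extension, torque-extension
    and superhelical-density response curves, per-state occupancies, and the
    DNA force-torque phase diagram.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
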