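Package: arptraj
Title: Conformational Order Parameters and Interface Analysis for Arp2/3
    Complex Activation Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the conformational changes that activate the
    Arp2/3 actin-nucleation complex from molecular dynamics trajectories and
    deposited structures: the Arp2-Arp3 inner-domain (short-pitch) distance,
    subunit twisting/flattening dihedrals, the ARPC2/ARPC4 clamp-twist
    dihedral, and named residue-pair distances, together with Shrake-Rupley
    solvent-accessible surface areas, buried interface areas, and sigmoidal
    per-residue contact scores. Includes a coarse-grained elastic-network
    surrogate of the steered (moving harmonic restraint) protocol that pulls
    the complex between its short-pitch and splayed conformations, and a
    synthetic-trajectory generator with recorded ground truth for validating
    every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml,
    zoo
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
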