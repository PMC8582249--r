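Package: smdrescore
Title: Rescoring Protein-Protein Docking Poses from Scaled Molecular
    Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Descriptor-based rescoring of candidate protein-protein
    docking poses from short scaled molecular dynamics (SMD)
    trajectories.  Computes interface descriptors on trajectory frames
    (interface root-mean-square deviation, buried surface area from a
    Shrake-Rupley solvent-accessible surface model, and the count of
    buried heavy atoms belonging to hydrophobic residues), classifies
    the stability of each trajectory, clusters poses on pairwise
    backbone interface RMSD with the Daura algorithm, and ranks poses
    with min-to-min, within-sigma and first-quartile figures of merit.
    A synthetic dimer and trajectory generator provides ground-truth
    ensembles so the whole pipeline is testable without running
    molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
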