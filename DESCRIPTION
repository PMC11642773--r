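Package: confeff
Title: Conformation-Fraction Models of Receptor Signaling Efficacy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps ensembles of receptor-ligand configurations to quantitative
    signaling efficacies along two transduction pathways. Configurations are
    described by three feature blocks (backbone/side-chain torsions, pairwise
    alpha-carbon distances, hydrogen-bond donor-acceptor distances), combined
    into a periodicity-aware normalized distance, and clustered into
    intracellular-pocket conformations by complete-linkage agglomeration
    followed by spectral grouping of cluster medoids under a Gaussian
    similarity of their superposed RMSDs. Per-ligand conformation occupancy
    fractions enter a multiple linear regression of efficacy, trained and
    validated with nested leave-one-out cross-validation and a hyperparameter
    grid search. Efficacy response functions and general/selective activation
    scores rank structural features linked to activation. A seeded synthetic
    ensemble generator with planted conformations makes the whole pipeline
    testable without molecular-dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
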