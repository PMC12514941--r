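Package: mdstab
Title: Biophysical Ranking of Stabilizing Point Mutations from Structure Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A secondary filter for protein thermostability engineering.
    Candidate point mutations pre-selected by a primary stability predictor
    are re-ranked by comparing biophysical metrics computed over structure
    ensembles (molecular dynamics snapshots) of each mutant against the wild
    type: hydrogen-bond network energy and unsatisfied donors/acceptors,
    backbone and sidechain flexibility (RMSF) normalized against per-amino-acid
    benchmark curves, hydrophobic surface exposure, helix propensity and
    capping, disulfide bridges, and salt bridges.  Includes the benchmark-curve
    construction machinery (Gaussian KDE with a monotone envelope), a
    composite z-score-style ranking, stability-weighted ROC evaluation with
    combinatorial AUC bounds for partially untested mutation sets, a
    cross-validated machine-learning re-ranking harness, and a synthetic
    fixture generator (ideal peptides, seeded jitter trajectories, toy
    hydrogen-bond and salt-bridge systems) so the whole package can be
    exercised without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    caret,
    e1071,
    randomForest,
    glmnet,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
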