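Package: dcna
Title: Difference and Multiensemble Contact Network Analysis of
    Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue-residue contact network analysis of molecular dynamics
    conformational ensembles. Estimates per-ensemble contact probabilities
    from trajectory frames (heavy-atom distance cutoff with a sequence
    separation rule), builds a consensus contact network from contacts that
    are stably formed in every ensemble, partitions it into residue
    communities by Girvan-Newman edge-betweenness removal with modularity
    maximization, computes difference contact networks (dCNA) between
    perturbed and reference ensembles at the community level, and correlates
    residue-pair and community-pair contact probabilities across many
    ligand-bound ensembles with the logarithm of experimental activity
    constants to rank function-linked contacts. Includes trajectory
    post-processing (superposition, RMSD, RMSF, equilibration slicing) and a
    synthetic-data generator with planted community structure and planted
    activity-responsive contacts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
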