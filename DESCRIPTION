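Package: coopbind
Title: Cooperative Binding Analysis of Protein-Ligand Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("coopbind", "developers", email = "coopbind@example.org",
           role = c("aut", "cre"))
Description: End-state binding free energy estimation (MM-PB/SA and MM-GB/SA)
    with per-residue decomposition, pi-pi stacking geometry statistics,
    close-contact occupancy, hydrogen-bond and RMSD/RMSF analyses for
    protein-ligand conformational ensembles, aimed at normal versus
    cooperative (two-copy) ligand binding studies such as CYP3A4 with
    ketoconazole. Includes a synthetic-ensemble generator with ground-truth
    manifests so every analysis stage is testable without molecular dynamics
    trajectories, a generalized Born implicit-solvation model with pairwise
    descreening, a finite-difference linearized Poisson-Boltzmann solver,
    and Shrake-Rupley solvent-accessible surface areas.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
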