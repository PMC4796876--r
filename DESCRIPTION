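Package: meltshift
Title: Predicting Protein Melting-Temperature Changes upon Point Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the change in protein melting temperature (delta-Tm)
    caused by single point mutations, from the wild-type three-dimensional
    structure alone or together with the wild-type melting temperature.
    Derives standard and temperature-dependent knowledge-based statistical
    potentials (mean-force potentials over residue distances, solvent
    accessibilities and backbone torsion domains) from sets of protein
    structures, combines them through two shallow neural-network model
    structures with sigmoid accessibility weights, and provides training by
    gradient descent with random restarts and early stopping, nested
    cross-validation, evaluation metrics with outlier trimming and
    accessibility stratification, two-state Gibbs-Helmholtz thermodynamics,
    and a synthetic-data generator so the whole pipeline can be exercised
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
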