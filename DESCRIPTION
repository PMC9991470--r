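Package: eggchem
Title: Chemometric Discrimination of Free-Range and Caged Eggs from
    Eggshell Elemental Profiles
Version: 0.1.0
Authors@R:
    person("eggchem", "maintainers", email = "eggchem@example.org",
           role = c("aut", "cre"))
Description: A reproducible chemometrics pipeline for authenticating egg
    husbandry class (free-range versus caged) from 16-element ICP-AES
    eggshell profiles. Implements robust Stahel-Donoho outlyingness
    screening via random projections, Kennard-Stone maximin sample-set
    partitioning, principal component exploration, PLS-DA and RBF-kernel
    least-squares SVM classifiers tuned by Monte Carlo cross-validation,
    and confusion-matrix performance metrics. Ships a synthetic-data
    generator emulating reference class-conditional element
    distributions (including detection-limit censoring and triplicate
    measurement structure) so the full workflow is testable without
    access to the original laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
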