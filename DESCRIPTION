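Package: wtfdrive
Title: Meiotic Drive Dynamics Under Inbreeding in Fission Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the spread of wtf-family meiotic drivers in populations
    with partial same-clone mating. Provides the deterministic one-locus
    allele-frequency recursion with an inbreeding coefficient, invasion
    thresholds for drivers linked to deleterious alleles, stochastic
    Wright-Fisher simulations of drive in finite haploid populations,
    estimators of inbreeding coefficients and mating efficiency from
    microscopy and progeny-genotyping count data, and maximum-likelihood
    estimation of linked fitness costs from experimental-evolution allele
    frequency trajectories. A synthetic-data module generates count tables
    and trajectories with the statistical structure the estimators assume,
    so every analysis stage can be exercised and calibrated without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
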