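Package: cmimpute
Title: Cross-Species Imputation of Species-Tissue Mean DNA Methylation
    with a Conditional Variational Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Imputes species-tissue "combination mean" DNA methylation
    samples for species-tissue pairs that were never profiled on the
    mammalian methylation array.  A conditional variational autoencoder
    is trained on individual beta-value samples labelled by species and
    tissue; imputation decodes a standard-normal latent draw together
    with the one-hot label of the target combination.  The package also
    provides the species/tissue/global mean baselines and a per-probe
    weighted logistic regression baseline, sample-wise and probe-wise
    agreement metrics, probe variance profiles with quartile
    stratification, species/tissue signal AUCs, grouped cross-validation
    over species-tissue combinations, leave-one-species-out regression
    of log maximum lifespan on combination mean methylation, and a
    seeded synthetic compendium generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
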