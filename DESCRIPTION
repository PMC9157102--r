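Package: suppdrive
Title: Population Dynamics and Fitness Inference for Homing Suppression
    Gene Drives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic models of a CRISPR homing
    suppression gene drive targeting a haplosufficient female-fertility
    gene, in a split-Cas9 design with an unlinked off-target locus.
    Provides the discrete-generation, sex-structured genotype-frequency
    recursion with germline conversion, germline and embryo resistance
    allele formation, and five fitness-cost models; genetic-load and
    suppression-equilibrium calculators; maximum-likelihood fitting of
    fitness costs and of the functional ("r1") resistance fraction to
    per-generation drive-carrier counts from cage populations, with AICc
    model comparison and profile-likelihood confidence intervals;
    estimators that turn cross counts into drive conversion and embryo
    resistance rates; and Wright-Fisher style simulators of the cage and
    artificial-selection study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
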