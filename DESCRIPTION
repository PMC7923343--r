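Package: admixpanel
Title: Small SNP Panels for Breed Proportion Estimation and Parentage
    Assignment in Admixed Cattle
Version: 0.1.0
Authors@R:
    person("ADMIXPANEL", "Developers", email = "admixpanel@example.org",
           role = c("aut", "cre"))
Description: Tools to design and evaluate small ancestry-informative SNP
    panels for admixed dairy cattle populations with a three-way ancestral
    structure (European taurine, African taurine, indicine). Implements
    panel selection by absolute allele-frequency differences with weighted
    ancestral pooling and split-fraction combination, stepwise pruning by
    physical distance, a supervised maximum-likelihood estimator of
    individual admixture proportions, and parentage assignment from
    opposing homozygotes with the separation value and the powers of
    assignment and exclusion. Includes a Balding-Nichols genotype
    simulator producing reference breeds, crossbreds with known ancestry
    and parent-offspring families, plus PLINK text and TSV genotype I/O
    and a command-line pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
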