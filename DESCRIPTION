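Package: driverBayes
Title: Base-Level Bayesian Modeling of Positive Selection for Cancer Driver
    Gene Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects cancer driver genes from cohort-aggregated somatic
    single-nucleotide mutation counts. A background mutation model combines a
    log-linear rate model over mutation types and genomic covariates with
    Gamma-distributed gene-specific effects fit by marginal maximum likelihood
    on synonymous sites. Hypothesis-specific selection models (oncogene, tumor
    suppressor, non-driver) rescale non-synonymous rates through log-linear
    functional-feature effects, with an optional two-state hidden Markov model
    capturing mutation hotspots. Genes are ranked by Bayes factors and called
    under Bayesian false discovery rate control. Includes a ground-truth
    simulator of exome-scale mutation data for power and calibration studies,
    simple dN/dS and clustering tests, and a benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Rcpp, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
biocViews: SomaticMutation, StatisticalMethod, Bayesian, DriverMutation
RoxygenNote: 7.3.3
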