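Package: PatientBoolNet
Title: Patient-Specific Boolean Network Models of Androgen Receptor
    Inhibition in Prostate Cancer
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Omics-driven personalization and continuous-time stochastic
    simulation of Boolean signaling networks, with in-silico gene knockout
    experiments for prostate cancer. Converts per-patient mutation, copy-number
    and expression data into subject-specific logical models, simulates them as
    asynchronous continuous-time Markov jump processes (Monte Carlo ensembles
    and an exact master-equation solver), quantifies perturbation response with
    the per-node percent change in area under the activity curve, and compares
    patient groups with a filtered Mann-Whitney / Benjamini-Hochberg procedure.
    Also implements methylation array beta/M-value conversion, representative
    probe selection for differentially methylated regions, and stratified
    Spearman correlation of methylation with expression, plus a synthetic
    multi-omics cohort generator with planted group effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
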