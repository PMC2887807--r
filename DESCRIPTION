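Package: pssmphos
Title: Phosphorylation Site Prediction from Evolutionary Sequence Profiles
Version: 0.1.0
Authors@R: person("pssmphos", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Kinase-independent prediction of protein phosphorylation sites
    (serine, threonine and tyrosine) from evolutionary information alone.
    Candidate sites are encoded as flattened windows of PSI-BLAST
    position-specific scoring matrix (PSSM) rows and classified with
    per-residue support vector machines using a radial basis function
    kernel.  The package includes readers for the blastpgp ASCII PSSM
    dialect, a formal negative-site labeling rule with an exclusion zone
    around annotated phosphosites, stride-based class-imbalance reduction,
    stratified k-fold cross-validation with standard confusion-matrix
    metrics (accuracy, sensitivity, specificity, Matthews correlation
    coefficient, false positive rate, Q3), a synthetic phosphoproteome
    generator for self-contained benchmarking, and a command-line
    orchestration layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
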