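Package: AdmixScan
Title: Local-Ancestry Deviation Scans and Drift Calibration for Admixed
    Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects candidate targets of post-admixture selection in
    recently admixed populations from local-ancestry call matrices. At
    each SNP the local ancestry fraction is tested against the
    genome-wide mean with a one-tailed binomial score test; a
    Beta-binomial drift-plus-sampling variance model yields a
    moment-matching estimator of the effective population size; and a
    forward-time Wright-Fisher tract simulator of single-pulse
    three-way admixture provides the neutral null distribution of the
    most extreme ancestry deviation, so that observed peaks can be
    judged against what genetic drift alone can produce.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
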