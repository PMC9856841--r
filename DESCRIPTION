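Package: sigsurv
Title: Gene-Signature Module Scores and Optimal-Cutpoint Survival Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives differentially expressed gene signatures from two-arm
    expression experiments, computes signed-weight module scores on
    independent cohorts with quantile rescaling, stratifies patients by
    maximally selected rank statistics or median cutoffs, and estimates
    Kaplan-Meier curves and Cox hazard ratios with Wald tests. Includes a
    synthetic-data generator for xenograft-style two-arm experiments and
    survival cohorts with score-dependent hazard, so every stage of the
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: survival, stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
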