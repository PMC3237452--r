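Package: perfuseSPM
Title: Statistical Process Monitoring of Liver Machine-Perfusion
    Metabolomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Multiway principal component analysis (MPCA) of dynamic
    metabolite trajectories collected during normothermic machine
    perfusion, with offline and online squared prediction error (SPE)
    statistics under scaled chi-squared control limits, a log10(SPE)
    ischemia index, contribution diagnostics for fault isolation, multiway
    partial least squares discriminant analysis (NIPALS) with variable
    importance in the projection, and case-resampling cross-validation of
    the classifier. Includes a synthetic generator of fresh and
    warm-ischemic perfusion batches for simulation studies.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
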