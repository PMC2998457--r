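Package: madecrc
Title: Capture-Recapture Estimation of Pregnancy-Related Mortality from
    Dual Informant Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the MADE-IN/MADE-FOR approach to measuring maternal
    mortality where vital registration is absent: two village informant
    networks independently list deaths of women of reproductive age, listings
    are deduplicated and cross-matched, follow-up visits verify which deaths
    are eligible pregnancy-related deaths, and capture-recapture analysis on
    the verified overlap estimates total deaths, per-network coverage, and the
    maternal mortality ratio. Includes Lincoln-Petersen and Chapman point
    estimators, a Bayesian two-stratum capture-recapture model with an exact
    grid posterior and a Gibbs sampler for uncertainty, informant
    classification-accuracy metrics against the verification gold standard,
    live-birth and cost-efficiency calculations, and a simulator of
    informant-based death capture for validation and survey design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
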