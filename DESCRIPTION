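Package: steti
Title: Survival Time Trend Estimation with Start Time End Time Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates and projects trends of improvement in N-year average
    survival time from cancer-registry style case listings. Recent
    diagnosis-year cohorts are right censored because their follow-up window
    has not elapsed, so conventional trend fits must discard the newest data.
    Start Time End Time Integration (STETI) fits a trend model to the
    completed diagnosis-year cohorts, transforms it algebraically into an
    equivalent death-year model, regresses the single steepness parameter on
    death-year cohorts (which contain no within-window right censoring), and
    transforms the result back into an updated diagnosis-year projection
    curve. The package provides cohort-table construction from patient
    records, linear, exponential, and logistic trend families, AIC-based
    model comparison via relative likelihoods, relative-likelihood
    uncertainty bands, retrospective hold-out validation, and a synthetic
    registry-data generator with known ground-truth trends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
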