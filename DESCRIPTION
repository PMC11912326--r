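Package: popmetab
Title: Pollutant Mixtures, the Adipose Metabolome, and Blood Pressure
    Change via Quantile G-Computation and Meet-in-the-Middle Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linking lipophilic persistent organic pollutant
    (POP) mixtures measured in adipose tissue to blood-pressure changes
    through the adipose metabolome. Implements linear quantile
    g-computation for overall mixture effects with per-chemical partial
    effects, dual metabolome-wide association scans (mixture on features,
    features on outcome), a Kaiser-Guttman effective-number-of-tests
    multiplicity correction, LC-HRMS feature annotation by m/z ppm and
    retention-time tolerance, meet-in-the-middle overlap of the two scans,
    and hypergeometric pathway overrepresentation. Includes a synthetic
    study generator (Gaussian-copula correlated log-normal exposures with
    limit-of-detection censoring, metabolic features with planted mixture
    effects and mediators, longitudinal blood pressure) so the whole
    pipeline is testable with known ground truth, plus preprocessing:
    LOD/sqrt(2) substitution, detection-rate and QC coefficient-of-
    variation feature filters, half-minimum imputation, and percent-change
    outcome construction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
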