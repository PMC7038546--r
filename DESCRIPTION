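Package: dmtype
Title: Rule-Based Classification of Type 1 and Type 2 Diabetes from
    Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify diabetes type (type 1 versus type 2) from
    longitudinal electronic health record event tables using deterministic
    phenotyping rules: ICD-9 code-ratio algorithms, insulin-prescription
    algorithms, and boolean combinations of the two.  Includes cohort
    construction from raw encounter, prescription, laboratory and delivery
    tables (onset detection with gestational and inpatient-glucose
    exclusions), validation machinery (confusion matrices, exact
    Clopper-Pearson confidence intervals, Cohen's kappa, age-stratified
    test characteristics, smoothed proportion-versus-age curves), the
    derivation-cohort algorithm-selection procedure, and a seeded synthetic
    EHR generator so the whole pipeline can be exercised end to end without
    access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
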