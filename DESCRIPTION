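Package: hospflow
Title: Gravity Models of Patient Flows to Hospitals for Complex Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates origin-destination gravity models of where patients
    undergo complex surgery (distance-only, distance plus hospital volume,
    and distance plus volume plus hospital characteristics), using a two-way
    fixed-effects double-demeaning estimator on aggregated patient flows.
    Predicts each patient's hospital from the fitted models, evaluates
    top-k prediction accuracy, per-patient model-sufficiency classes,
    subgroup comparison tables, and travel-distance bias. Includes a
    seeded synthetic patient-flow generator (ZIP geographies, hospitals
    with latent attractiveness, multinomial-logit choices) so the full
    pipeline is testable without restricted inpatient data.
License: MIT
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), geosphere, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
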