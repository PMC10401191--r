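Package: anctriage
Title: Traffic-Light Triage and Trial Feasibility Tools for Community
    Antenatal Care
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale rules engine for community health worker
    antenatal and postnatal home visits: guideline-encoded traffic-light
    classification of anemia (hemoglobin), hypertensive disorders of
    pregnancy (blood pressure and shock index), and gestational diabetes
    (nonfasting 2-hour OGTT), with referral recommendation texts,
    visit-window scheduling, a two-step validation harness against a
    structurally independent oracle, a synthetic two-arm cluster-trial
    cohort simulator with exact-count enforcement, and feasibility and
    clinical summary statistics for pilot trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
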