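Package: psmcea
Title: Partitioned-Survival Cost-Effectiveness Modelling for First-Line
    Immunochemotherapy in Advanced Non-Squamous NSCLC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for trial-based partitioned-survival
    cost-effectiveness analysis: reconstruction of pseudo individual-patient
    data from digitized Kaplan-Meier coordinates and numbers-at-risk tables
    (Guyot algorithm), maximum-likelihood fitting and AIC/BIC selection among
    six parametric survival families, a three-state (progression-free /
    progressed / dead) partitioned-survival model on a 21-day cycle with
    discounting, a fully itemized cost engine, and base-case, one-way
    deterministic (tornado) and probabilistic (CEAC) sensitivity analyses.
    Ships a synthetic two-arm trial generator emulating first-line
    camrelizumab plus chemotherapy versus chemotherapy in advanced
    non-squamous NSCLC, so the whole pipeline is reproducible end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    survival,
    flexsurv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
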