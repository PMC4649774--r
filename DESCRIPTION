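Package: igegroup
Title: Latent Component Groups from Component-Resolved IgE Sensitization
    Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clusters allergen components into component groups (CGs) from a
    child-by-component matrix of specific-IgE positivity, using a Bayesian
    latent-variable model fitted by variational inference with an
    exact-enumeration oracle for small instances. Discretizes raw ISAC
    standardized units (ISU), applies prevalence filters, scores each child's
    posterior sensitization to every CG, quantifies cluster stability under
    subject resampling, and relates CG sensitization to clinical outcomes
    (asthma, wheeze, hay fever, eczema, lung function, exhaled nitric oxide)
    by multivariate logistic and linear regression. Includes a calibrated
    synthetic-cohort generator so the full pipeline is testable without
    cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    emmeans
Config/testthat/edition: 3
RoxygenNote: 7.3.3
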