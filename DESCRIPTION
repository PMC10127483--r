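Package: earplast
Title: Phenotypic Plasticity Analysis of Maize Ear Traits in Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the phenotypic plasticity of maize ear traits in
    multi-environment trials of transgenic inbred populations. Implements
    Finlay-Wilkinson regression with both an alternating least-squares estimator
    and a Gibbs sampler for the Bayesian hierarchical formulation, per-line
    plasticity summaries (genetic value, linear plasticity, nonlinear plasticity),
    a candidate-gene screening cascade relative to a wild-type reference, AMMI
    stability analysis with AMMI stability values, measurement-quality metrics for
    phenotyping platforms, and a multi-environment trial simulator with known
    ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
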