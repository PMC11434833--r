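Package: peritopk
Title: Population Pharmacokinetics and Target Attainment of Continuously
    Infused Piperacillin-Tazobactam Under Open-Abdomen Negative-Pressure
    Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for population pharmacokinetic/pharmacodynamic analysis of
    continuously infused piperacillin-tazobactam in critically ill patients
    managed with an open abdomen and vacuum-assisted wound closure. Implements
    a two-compartment plasma-peritoneal structural model with elimination from
    both compartments, a log-normal covariate model with inter-individual and
    inter-occasion variability and proportional residual error, SAEM
    population estimation with MAP priors, fixed parameters, likelihood-ratio
    covariate testing, subject-level bootstrap and simulation-based
    diagnostics (weighted residuals, NPDE, VPC), non-compartmental exposure
    metrics (calculated urinary/VAC clearances, peritoneal diffusion,
    underdosing classification), a Monte Carlo probability-of-target-attainment
    engine over renal-function groups, dosing regimens and MIC grids, and a
    synthetic-cohort generator emulating the sparse T0/T1 multi-matrix
    sampling design so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
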