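# peritopk

Population pharmacokinetics and pharmacodynamic target attainment of
continuously infused piperacillin–tazobactam in critically ill patients
managed with an open abdomen and vacuum-assisted wound closure (OA/VAC).

Negative-pressure dressings drain peritoneal fluid continuously, so they
add a potential elimination route at the very site an intra-abdominal
infection is treated. For a time-dependent beta-lactam the clinical
target is unbound concentration above the pathogen's MIC for 100% of the
dosing interval (100% fT>MIC) — under continuous infusion, simply
`Css > MIC` — in plasma and in peritoneal fluid. `peritopk` is for
pharmacometricians and ICU researchers who want to fit, check and
exercise this model end to end.

## The model

Two compartments (plasma, peritoneal) with elimination from both:

    dA1/dt = R(t) − (k10 + k12) A1 + k21 A2
    dA2/dt = k12 A1 − (k21 + k20) A2

with k10 = Cl1/V1 (renal/RRT), k12 = Q/V1, k21 = Q/V2, k20 = Cl2/V2
(drainage route). The population layer is log-normal with age and weight
on V1 and renal-function category on Cl1 (piperacillin), inter-individual
variability on V1, Cl1, Cl2, inter-occasion variability on Cl1, and
proportional residual error per compartment; V2 is fixed at 5 L, and
MAP priors anchor V1 and (for piperacillin) Q around 20. At steady state

    C1ss = R / (Cl1 + Q·Cl2/(Q + Cl2)),   C2ss/C1ss = Q/(Q + Cl2).

The package provides: exact closed-form simulation of the kinetics
(`simulate_profile()`, `steady_state()`), a synthetic-cohort generator
emulating the sparse clinical design (`generate_cohort()`), SAEM
population estimation with fixed parameters, MAP priors and a
censoring-aware likelihood (`fit_population()`), likelihood-ratio
covariate testing and subject-level bootstrap (`lrt_compare()`,
`bootstrap_ci()`), simulation-based diagnostics — weighted residuals,
NPDE, prediction-corrected VPC (`model_diagnostics()`) —
non-compartmental exposure metrics (`calculated_clearance()`,
`diffusion_ratio()`, `classify_underdosing()`), and a Monte Carlo
PTA/FTA engine over regimens, renal groups, compartments and MIC grids
(`simulate_pta()`, `compute_fta()`, `ecoff_report()`). The whole chain
runs from one configuration via `run_pipeline()`.

## Worked example

A typical 66-year-old, 83-kg patient with normal renal function on
16 g/day continuous piperacillin:

```r
library(peritopk)
pop <- pip_reference_params()
p <- individual_params(pop, covariate_vector(age = 66, weight = 83,
                                             renal_cat = "A"))
p
#> Two-compartment structural parameters (mg, L, h):
#>   V1 = 30.25 L   V2 = 5 L
#>   Q  = 23.83 L/h Cl1 = 38.74 L/h  Cl2 = 5.567 L/h
steady_state(p, 16000 / 24)
#>     C1ss     C2ss
#> 15.41359 12.49497
```

Plasma steady state is 15.4 mg/L and peritoneal 12.5 mg/L — a peritoneal
diffusion ratio of 81% (100·Q/(Q+Cl2)); this typical patient sits above
the 8 mg/L Enterobacteriaceae cut-off at the infection site but below
the 16 mg/L Pseudomonas cut-off. Population variability turns that into
a probability:

```r
g <- simulate_pta(pop, default_regimens()$`16g`, group = "A",
                  n = 10000, seed = 42)
subset(g, compartment == "C2" & multiplier == 1)[, c("mic", "pta")]
#>  mic   pta
#>    1 99.98
#>    2 99.42
#>    4 94.32
#>    8 73.42
#>   16 35.61
#>   32  6.58
#>   64  0.16
```

So at 16 g/day, 73% of group-A patients exceed a peritoneal MIC of
8 mg/L for the full interval, and 36% exceed 16 mg/L. Weighting by a
pathogen MIC distribution gives a fractional target attainment with the
\>85% success rule:

```r
compute_fta(subset(g, compartment == "C2" & multiplier == 1),
            data.frame(mic = c(2, 4, 8, 16), freq = c(.3, .3, .3, .1)))
#> $fta
#> [1] 83.7  # percent; success FALSE (not > 85)
```

A full synthetic study — generate 45 patients, fit both drugs, run
diagnostics, exposure summaries and PTA grids — is one call:

```r
cfg <- run_config(list(n_patients = 45,
                       seeds = list(cohort = 1, fit = 2,
                                    diagnostics = 3, pta = 4)))
res <- run_pipeline(cfg, "run1")
```

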