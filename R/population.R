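#' Population pharmacokinetic parameters
#'
#' Fixed effects, covariate coefficients, variability terms and residual
#' error parameters for one drug of the piperacillin--tazobactam pair. The
#' individual model is log-normal throughout:
#' \deqn{\log V_1 = \log V_{1,pop} + \beta_{V1,age}\,age + \beta_{V1,wt}\,wt + \eta_{V1}}
#' \deqn{\log Cl_1 = \log Cl_{1,pop} + \beta_{catB} 1_B + \beta_{catC} 1_C + \eta_{Cl1} + \kappa_{occ}}
#' \deqn{\log Cl_2 = \log Cl_{2,pop} + \eta_{Cl2}}
#' with V2 and (for tazobactam) Q fixed, and proportional residual error
#' `y = c (1 + b eps)` with compartment-specific `b`.
#'
#' Covariates enter uncentered by default; set `centered = TRUE` to code
#' age/weight as deviations from the cohort medians (66 years, 83 kg).
#'
#' @param drug drug label, `"PIP"` or `"TAZ"`.
#' @param V1pop,V2pop,Qpop,Cl1pop,Cl2pop population fixed effects (L, L,
#'   L/h, L/h, L/h).
#' @param betaV1_age,betaV1_weight covariate coefficients on log V1
#'   (1/year, 1/kg).
#' @param betaCl1_age optional age coefficient on log Cl1 (1/year); the
#'   final piperacillin model excludes it (0).
#' @param betaCl1_catB,betaCl1_catC log-scale renal-category effects on Cl1
#'   (CRRT and moderate impairment, vs the normal/augmented reference).
#' @param omegaV1,omegaCl1,omegaCl2 SDs of log-scale inter-individual
#'   variability, >= 0.
#' @param gammaCl1 SD of log-scale inter-occasion variability on Cl1, >= 0.
#' @param bC1,bC2 proportional residual error for plasma and peritoneal
#'   observations, >= 0.
#' @param fixed character vector of fixed (non-estimated) fixed effects.
#' @param priors named list of MAP priors, each `c(mean, sd)` on the natural
#'   scale, e.g. `list(V1pop = c(20, 1))`.
#' @param centered logical; covariate centering mode (see Details).
#' @return An object of class `population_params`.
#' @seealso [pip_reference_params()], [taz_reference_params()]
#' @export
population_params <- function(drug,
                              V1pop, V2pop = 5, Qpop, Cl1pop, Cl2pop,
                              betaV1_age = 0, betaV1_weight = 0,
                              betaCl1_age = 0,
                              betaCl1_catB = 0, betaCl1_catC = 0,
                              omegaV1 = 0, omegaCl1 = 0, omegaCl2 = 0,
                              gammaCl1 = 0,
                              bC1 = 0, bC2 = 0,
                              fixed = "V2pop",
                              priors = list(),
                              centered = FALSE) {
  drug <- match.arg(drug, c("PIP", "TAZ"))
  for (nm in c("V1pop", "V2pop", "Qpop", "Cl1pop"))
    assert_num(get(nm), nm, positive = TRUE, len = 1)
  assert_num(Cl2pop, "Cl2pop", nonneg = TRUE, len = 1)
  for (nm in c("omegaV1", "omegaCl1", "omegaCl2", "gammaCl1", "bC1", "bC2"))
    assert_num(get(nm), nm, nonneg = TRUE, len = 1)
  structure(list(drug = drug,
                 V1pop = V1pop, V2pop = V2pop, Qpop = Qpop,
                 Cl1pop = Cl1pop, Cl2pop = Cl2pop,
                 betaV1_age = betaV1_age, betaV1_weight = betaV1_weight,
                 betaCl1_age = betaCl1_age,
                 betaCl1_catB = betaCl1_catB, betaCl1_catC = betaCl1_catC,
                 omegaV1 = omegaV1, omegaCl1 = omegaCl1, omegaCl2 = omegaCl2,
                 gammaCl1 = gammaCl1, bC1 = bC1, bC2 = bC2,
                 fixed = fixed, priors = priors, centered = centered),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf("Population PK parameters (%s)%s:\n", x$drug,
              if (x$centered) ", centered covariates" else ""))
  cat(sprintf("  V1pop %.4g L  V2pop %.4g L (%s)  Qpop %.4g L/h%s\n",
              x$V1pop, x$V2pop,
              if ("V2pop" %in% x$fixed) "fixed" else "estimated",
              x$Qpop, if ("Qpop" %in% x$fixed) " (fixed)" else ""))
  cat(sprintf("  Cl1pop %.4g L/h  Cl2pop %.4g L/h\n", x$Cl1pop, x$Cl2pop))
  cat(sprintf("  betaV1: age %.4g, weight %.4g; betaCl1: catB %.4g, catC %.4g\n",
              x$betaV1_age, x$betaV1_weight, x$betaCl1_catB, x$betaCl1_catC))
  cat(sprintf("  omega (V1, Cl1, Cl2) = %.3g, %.3g, %.3g; gammaCl1 = %.3g\n",
              x$omegaV1, x$omegaCl1, x$omegaCl2, x$gammaCl1))
  cat(sprintf("  proportional error b (plasma, peritoneal) = %.3g, %.3g\n",
              x$bC1, x$bC2))
  invisible(x)
}

#' Reference population estimates for piperacillin
#'
#' Final population estimates for unbound piperacillin in critically ill
#' open-abdomen/VAC patients on continuous infusion: age and total body
#' weight on V1, renal-function category on Cl1, MAP priors N(20, 1) on
#' V1pop and N(20, 3) on Qpop, V2 fixed at 5 L.
#'
#' @return A [population_params()] object.
#' @export
pip_reference_params <- function() {
  population_params("PIP",
                    V1pop = 21.213, V2pop = 5, Qpop = 23.833,
                    Cl1pop = 38.739, Cl2pop = 5.567,
                    betaV1_age = -0.016, betaV1_weight = 0.017,
                    betaCl1_catB = -2.016, betaCl1_catC = -1.243,
                    omegaV1 = 0.225, omegaCl1 = 0.661, omegaCl2 = 0.123,
                    gammaCl1 = 0.391, bC1 = 0.207, bC2 = 0.239,
                    fixed = "V2pop",
                    priors = list(V1pop = c(20, 1), Qpop = c(20, 3)))
}

#' Reference population estimates for tazobactam
#'
#' Final population estimates for unbound tazobactam: renal-function
#' category on Cl1, no covariates on V1, V2 fixed at 5 L and Q fixed at
#' 20 L/h, MAP prior N(20, 5) on V1pop.
#'
#' @return A [population_params()] object.
#' @export
taz_reference_params <- function() {
  population_params("TAZ",
                    V1pop = 23.248, V2pop = 5, Qpop = 20,
                    Cl1pop = 7.013, Cl2pop = 3.003,
                    betaCl1_catB = -5.602, betaCl1_catC = -2.303,
                    omegaV1 = 0.351, omegaCl1 = 0.569, omegaCl2 = 0.243,
                    gammaCl1 = 0.967, bC1 = 0.371, bC2 = 0.372,
                    fixed = c("V2pop", "Qpop"),
                    priors = list(V1pop = c(20, 5)))
}

#' Individual covariates
#'
#' @param age age (years), > 0.
#' @param weight total body weight (kg), > 0.
#' @param renal_cat renal-function category: `"A"` normal (60 < CLcr <=
#'   150 mL/min), `"B"` CRRT, `"C"` moderate impairment (30 < CLcr <= 60),
#'   `"D"` augmented clearance (> 150). D is remapped to A before model
#'   evaluation (reference pooling).
#' @param occasion sampling occasion index (1 = loading/T0 window, 2 = T1
#'   window).
#' @return An object of class `covariate_vector`.
#' @export
covariate_vector <- function(age, weight, renal_cat = "A", occasion = 1L) {
  assert_num(age, "age", positive = TRUE, len = 1)
  assert_num(weight, "weight", positive = TRUE, len = 1)
  if (!renal_cat %in% c("A", "B", "C", "D"))
    stopf("unknown renal category '%s'", renal_cat)
  structure(list(age = age, weight = weight, renal_cat = renal_cat,
                 occasion = as.integer(occasion)),
            class = "covariate_vector")
}

#' Per-individual random effects
#'
#' @param etaV1,etaCl1,etaCl2 log-scale inter-individual deviations.
#' @param etaOccCl1 numeric vector of log-scale inter-occasion deviations
#'   on Cl1, one per occasion.
#' @return An object of class `random_effects`. The zero vector is the
#'   typical individual.
#' @export
random_effects <- function(etaV1 = 0, etaCl1 = 0, etaCl2 = 0,
                           etaOccCl1 = c(0, 0)) {
  assert_num(etaV1, "etaV1", len = 1)
  assert_num(etaCl1, "etaCl1", len = 1)
  assert_num(etaCl2, "etaCl2", len = 1)
  assert_num(etaOccCl1, "etaOccCl1")
  structure(list(etaV1 = etaV1, etaCl1 = etaCl1, etaCl2 = etaCl2,
                 etaOccCl1 = etaOccCl1),
            class = "random_effects")
}

## Centering constants (cohort medians) used when pop$centered is TRUE.
AGE_REF <- 66
WT_REF <- 83

## age/weight coding under the model's centering mode
code_covariates <- function(pop, age, weight) {
  if (isTRUE(pop$centered)) list(age = age - AGE_REF, weight = weight - WT_REF)
  else list(age = age, weight = weight)
}

#' Map population parameters, covariates and random effects to an individual
#'
#' Applies the log-normal covariate model to obtain one individual's
#' structural parameters for a given occasion. Renal category D is treated
#' as the reference A.
#'
#' @param pop a [population_params()] object.
#' @param cov a [covariate_vector()].
#' @param eta a [random_effects()] object (defaults to the typical
#'   individual).
#' @return A [structural_params()] object.
#' @examples
#' pop <- pip_reference_params()
#' individual_params(pop, covariate_vector(66, 83, "A"))
#' @export
individual_params <- function(pop, cov, eta = random_effects()) {
  if (!inherits(pop, "population_params")) stopf("'pop' must be population_params")
  if (!inherits(cov, "covariate_vector")) stopf("'cov' must be covariate_vector")
  cat <- if (cov$renal_cat == "D") "A" else cov$renal_cat
  cc <- code_covariates(pop, cov$age, cov$weight)
  V1 <- pop$V1pop * exp(pop$betaV1_age * cc$age +
                        pop$betaV1_weight * cc$weight + eta$etaV1)
  kappa <- if (length(eta$etaOccCl1) >= cov$occasion)
    eta$etaOccCl1[cov$occasion] else 0
  Cl1 <- pop$Cl1pop * exp(pop$betaCl1_age * cc$age +
                          pop$betaCl1_catB * (cat == "B") +
                          pop$betaCl1_catC * (cat == "C") +
                          eta$etaCl1 + kappa)
  Cl2 <- pop$Cl2pop * exp(eta$etaCl2)
  structural_params(V1 = V1, V2 = pop$V2pop, Q = pop$Qpop,
                    Cl1 = Cl1, Cl2 = Cl2)
}

#' Draw random effects for a set of individuals
#'
#' Independent normal draws on the log scale with the population SDs
#' (no correlation between effects).
#'
#' @param pop a [population_params()] object.
#' @param n number of individuals, >= 1.
#' @param n_occasions number of occasions for the inter-occasion effect on
#'   Cl1.
#' @param seed optional integer seed for reproducibility.
#' @return A list of `n` [random_effects()] objects.
#' @export
sample_random_effects <- function(pop, n, n_occasions = 2, seed = NULL) {
  if (n < 1) stopf("'n' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ev <- stats::rnorm(n, 0, pop$omegaV1)
  e1 <- stats::rnorm(n, 0, pop$omegaCl1)
  e2 <- stats::rnorm(n, 0, pop$omegaCl2)
  ko <- matrix(stats::rnorm(n * n_occasions, 0, pop$gammaCl1),
               nrow = n, ncol = n_occasions)
  lapply(seq_len(n), function(i)
    random_effects(ev[i], e1[i], e2[i], ko[i, ]))
}

#' Apply proportional residual error
#'
#' Observation model `y = c (1 + b eps)`, `eps ~ N(0, 1)`, with `b = bC1`
#' for plasma and `b = bC2` for peritoneal observations. Draws below zero
#' are floored at 0 (with a warning), since concentrations cannot be
#' negative.
#'
#' @param true_conc true (model) concentrations, mg/L, >= 0.
#' @param compartment `"plasma"` or `"peritoneal"`.
#' @param pop a [population_params()] object supplying `bC1`/`bC2`.
#' @param seed optional integer seed.
#' @return Observed concentrations (mg/L), same length as `true_conc`.
#' @export
apply_residual_error <- function(true_conc, compartment = c("plasma", "peritoneal"),
                                 pop, seed = NULL) {
  compartment <- match.arg(compartment)
  assert_num(true_conc, "true_conc", nonneg = TRUE)
  if (!is.null(seed)) set.seed(seed)
  b <- if (compartment == "plasma") pop$bC1 else pop$bC2
  y <- true_conc * (1 + b * stats::rnorm(length(true_conc)))
  if (any(y < 0)) {
    warnf("%d proportional-error draw(s) below zero floored at 0", sum(y < 0))
    y <- pmax(y, 0)
  }
  y
}

#' Joint log density of one individual's data and random effects
#'
#' Sum of observation log densities `N(y; c, (b c)^2)` under the
#' proportional error model plus the normal log priors of the random
#' effects. Observations in non-modelled matrices (VAC fluid, urine) must
#' be excluded by the caller; only plasma (C1) and peritoneal (C2) enter.
#'
#' @param pop a [population_params()] object.
#' @param obs data frame with columns `time` (h), `matrix` (`"plasma"` or
#'   `"peritoneal"`), `value` (mg/L) and optionally `occasion`.
#' @param cov a [covariate_vector()] (its `occasion` field is ignored; the
#'   per-row `occasion` is used).
#' @param eta a [random_effects()] object.
#' @param schedule a [dose_schedule()] for the individual.
#' @param t_occ time (h) at which occasion 2 begins, default 24.
#' @return The joint log density (numeric scalar); `-Inf` when an
#'   observation is positive where the model predicts zero.
#' @export
log_likelihood <- function(pop, obs, cov, eta, schedule, t_occ = 24) {
  if (!all(obs$matrix %in% c("plasma", "peritoneal")))
    stopf("log_likelihood accepts plasma/peritoneal observations only")
  ## Cl1 switches from its occasion-1 to its occasion-2 value at t_occ with
  ## the compartment amounts carrying over.
  pr <- sim_occasions(pop, cov, eta, schedule, obs$time, t_occ)
  f <- ifelse(obs$matrix == "plasma", pr$C1, pr$C2)
  b <- ifelse(obs$matrix == "plasma", pop$bC1, pop$bC2)
  y <- obs$value
  if (any(f <= 0 & y > 0)) return(-Inf)
  ok <- f > 0
  ll <- sum(stats::dnorm(y[ok], f[ok], b[ok] * f[ok], log = TRUE))
  pr_eta <- 0
  if (pop$omegaV1 > 0) pr_eta <- pr_eta + stats::dnorm(eta$etaV1, 0, pop$omegaV1, log = TRUE)
  if (pop$omegaCl1 > 0) pr_eta <- pr_eta + stats::dnorm(eta$etaCl1, 0, pop$omegaCl1, log = TRUE)
  if (pop$omegaCl2 > 0) pr_eta <- pr_eta + stats::dnorm(eta$etaCl2, 0, pop$omegaCl2, log = TRUE)
  if (pop$gammaCl1 > 0) pr_eta <- pr_eta + sum(stats::dnorm(eta$etaOccCl1, 0, pop$gammaCl1, log = TRUE))
  ll + pr_eta
}

## Simulate an individual's profile across the occasion boundary: Cl1
## switches from its occasion-1 to occasion-2 value at t_occ, state carries
## over. Returns C1/C2 at 'times'.
sim_occasions <- function(pop, cov, eta, schedule, times, t_occ = 24) {
  cv1 <- cov; cv1$occasion <- 1L
  cv2 <- cov; cv2$occasion <- 2L
  p1 <- individual_params(pop, cv1, eta)
  p2 <- individual_params(pop, cv2, eta)
  k1 <- rate_constants(p1)
  k2 <- rate_constants(p2)
  bp <- sort(unique(c(0, schedule$start, schedule$start + schedule$duration,
                      t_occ, times)))
  bp <- bp[is.finite(bp)]
  rates <- segment_rates(schedule, bp)
  A1 <- 0; A2 <- 0
  sA1 <- numeric(length(bp)); sA2 <- numeric(length(bp))
  for (i in seq_along(bp)) {
    sA1[i] <- A1; sA2[i] <- A2
    if (i < length(bp)) {
      k <- if (bp[i] < t_occ) k1 else k2
      st <- twocpt_step(A1, A2, k["k10"], k["k12"], k["k21"], k["k20"],
                        rates[i], bp[i + 1] - bp[i])
      A1 <- st$A1; A2 <- st$A2
    }
  }
  idx <- match(times, bp)
  list(time = times, C1 = sA1[idx] / p1$V1, C2 = sA2[idx] / p1$V2)
}
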