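## shared small fixtures for estimation tests

near_noiseless_fit <- function() {
  pop <- population_params("PIP", V1pop = 25, Qpop = 22, Cl1pop = 12,
                           Cl2pop = 4, omegaV1 = 0.05, omegaCl1 = 0.05,
                           omegaCl2 = 0.05, gammaCl1 = 0,
                           bC1 = 0.03, bC2 = 0.03)
  des <- cohort_design(n_patients = 60,
                       rich_times = list(plasma = c(1, 2, 4, 8, 24, 60),
                                         peritoneal = c(1, 4, 60)))
  coh <- generate_cohort(des, pop_pip = pop, seed = 31)
  ## Q is fixed at its generating value: with equilibration far faster
  ## than any sampling time, Q and Cl2 are identified only through their
  ## ratio, so the free parameters are tested on an identifiable model
  spec <- fit_spec("PIP", estimate = c("V1pop", "Cl1pop", "Cl2pop"),
                   fixed_values = list(V2pop = 5, Qpop = 22),
                   priors = list(),
                   covariates = list(V1 = character(), Cl1 = character()),
                   iiv = c("V1", "Cl1", "Cl2"), iov = character(),
                   control = saem_control(n_burn = 150, n_smooth = 100,
                                          seed = 32))
  list(pop = pop, fit = fit_population(cohort_to_dataset(coh), spec))
}

test_that("near-noiseless rich-design data identify the free parameters", {
  r <- near_noiseless_fit()
  p <- r$fit$params
  expect_equal(p$V1pop, 25, tolerance = 0.025)
  expect_equal(p$Cl1pop, 12, tolerance = 0.025)
  expect_equal(p$Cl2pop, 4, tolerance = 0.04)
  expect_equal(p$bC1, 0.03, tolerance = 0.25)
  expect_equal(p$bC2, 0.03, tolerance = 0.25)
  ## fixed flags are honored bit-exactly
  expect_identical(p$V2pop, 5)
  expect_identical(p$Qpop, 22)
  expect_true(r$fit$converged)
})

test_that("likelihood prefers the generating parameters over a distorted set", {
  pop <- population_params("PIP", V1pop = 25, Qpop = 22, Cl1pop = 12,
                           Cl2pop = 4, omegaCl1 = 0.1, bC1 = 0.05,
                           bC2 = 0.05)
  des <- cohort_design(n_patients = 15,
                       rich_times = list(plasma = c(2, 8, 40)))
  coh <- generate_cohort(des, pop_pip = pop, seed = 41)
  dat <- cohort_to_dataset(coh)
  sch <- regimen_schedule(4000, 16000)
  ll_at <- function(cl1) {
    tot <- 0
    for (i in coh$subjects$id) {
      s <- coh$subjects[i, ]
      o <- dat[dat$ID == i & dat$EVID == 0 & dat$DRUG == "PIP" &
                 dat$MATRIX %in% c("plasma", "peritoneal"), ]
      p2 <- pop; p2$Cl1pop <- cl1
      tot <- tot + log_likelihood(
        p2, data.frame(time = o$TIME, matrix = o$MATRIX, value = o$DV),
        covariate_vector(s$age, s$weight, s$renal_cat),
        random_effects(), sch)
    }
    tot
  }
  expect_gt(ll_at(12), ll_at(24))
})

test_that("TAZ fixed parameters and MAP shrinkage behave as declared", {
  ## weak data + MAP prior: the V1pop estimate lies between the prior mean
  ## and the generating value
  pop <- taz_reference_params()
  pop$V1pop <- 30
  coh <- generate_cohort(cohort_design(n_patients = 15), pop_taz = pop,
                         seed = 13)
  spec <- fit_spec("TAZ", control = saem_control(n_burn = 120, n_smooth = 80,
                                                 seed = 14))
  fit <- fit_population(cohort_to_dataset(coh), spec)
  expect_identical(fit$params$V2pop, 5)
  expect_identical(fit$params$Qpop, 20)
  expect_gt(fit$params$V1pop, 20)
  expect_lt(fit$params$V1pop, 32)
})

test_that("likelihood-ratio comparison follows the chi-square reference", {
  f0 <- structure(list(logLik = -100, n_theta = 3), class = "pk_fit")
  f1 <- structure(list(logLik = -100, n_theta = 4), class = "pk_fit")
  expect_equal(lrt_compare(f0, f1)$p_value, 1)
  f2 <- structure(list(logLik = -100 + 3.841459 / 2, n_theta = 4),
                  class = "pk_fit")
  expect_equal(lrt_compare(f0, f2)$p_value, 0.05, tolerance = 1e-4)
  f3 <- structure(list(logLik = -101, n_theta = 4), class = "pk_fit")
  expect_warning(lrt_compare(f0, f3), "convergence")
  expect_error(lrt_compare(f1, f0), "more parameters")
})

test_that("bootstrap is seed-reproducible and degenerates with the noise", {
  ## a cohort of clones with (near) zero noise: resampling cannot move the
  ## estimate, so percentile intervals collapse onto it
  pop <- population_params("PIP", V1pop = 25, Qpop = 22, Cl1pop = 12,
                           Cl2pop = 4, omegaCl1 = 1e-4,
                           bC1 = 1e-3, bC2 = 1e-3)
  des <- cohort_design(n_patients = 8,
                       p_renal = c(A = 1, B = 0, C = 0, D = 0),
                       age_iqr = c(65.99, 66.01), age_median = 66,
                       weight_iqr = c(82.99, 83.01), weight_median = 83,
                       t1_range = c(60, 60.01),
                       rich_times = list(plasma = 30))
  coh <- generate_cohort(des, pop_pip = pop, seed = 21)
  dat <- cohort_to_dataset(coh)
  spec <- fit_spec("PIP", estimate = "Cl1pop",
                   fixed_values = list(V2pop = 5, Qpop = 22, V1pop = 25,
                                       Cl2pop = 4),
                   priors = list(),
                   covariates = list(V1 = character(), Cl1 = character()),
                   iiv = "Cl1", iov = character(),
                   control = saem_control(n_burn = 40, n_smooth = 30))
  b1 <- bootstrap_ci(dat, spec, n_reps = 10, seed = 5)
  b2 <- bootstrap_ci(dat, spec, n_reps = 10, seed = 5)
  expect_identical(b1$estimates, b2$estimates)
  expect_equal(b1$n_failed, 0)
  cl1 <- b1$ci[b1$ci$parameter == "Cl1pop", ]
  expect_lt((cl1$upper - cl1$lower) / cl1$median, 0.05)
  expect_equal(cl1$median, 12, tolerance = 0.05)
})

test_that("diagnostics recover perfect fits and refuse unstable NPDE", {
  pop <- population_params("PIP", V1pop = 25, Qpop = 22, Cl1pop = 12,
                           Cl2pop = 4, bC1 = 0, bC2 = 0)
  coh <- generate_cohort(cohort_design(n_patients = 20), pop_pip = pop,
                         seed = 17)
  dat <- cohort_to_dataset(coh)
  dpop <- pop; dpop$bC1 <- 1e-3; dpop$bC2 <- 1e-3
  spec <- fit_spec("PIP", priors = list(),
                   estimate = c("V1pop", "Cl1pop", "Cl2pop"),
                   fixed_values = list(V2pop = 5, Qpop = 22),
                   covariates = list(V1 = character(), Cl1 = character()),
                   iiv = c("V1", "Cl1", "Cl2"), iov = character())
  dg <- model_diagnostics(dpop, dataset = dat, spec = spec, n_sim = 100,
                          seed = 3)
  expect_gt(min(dg$r2$r2_population), 0.9999)
  expect_gt(min(dg$r2$r2_individual), 0.9999)
  expect_lt(max(abs(dg$residuals$iwres)), 0.05)
  expect_lt(max(abs(dg$residuals$pwres)), 0.75)
  expect_error(model_diagnostics(dpop, dataset = dat, spec = spec,
                                 n_sim = 20), ">= 50")
})
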