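#' SAEM estimation controls
#'
#' @param n_burn exploration iterations (step size 1, annealed variances).
#' @param n_smooth smoothing iterations (decreasing step sizes).
#' @param mh_steps Metropolis passes over the latent components per
#'   iteration.
#' @param anneal variance annealing factor during exploration (variances
#'   may not shrink faster than this per iteration).
#' @param seed integer seed for the stochastic E-step.
#' @param t_occ occasion-2 start time (h).
#' @return A list of class `saem_control`.
#' @export
saem_control <- function(n_burn = 300, n_smooth = 150, mh_steps = 2,
                         anneal = 0.95, seed = NULL, t_occ = 24) {
  structure(list(n_burn = n_burn, n_smooth = n_smooth, mh_steps = mh_steps,
                 anneal = anneal, seed = seed, t_occ = t_occ),
            class = "saem_control")
}

#' Estimation specification
#'
#' Declares which population parameters are estimated, which are fixed,
#' which carry MAP priors, the covariate model, and which parameters carry
#' inter-individual (IIV) and inter-occasion (IOV) random effects.
#'
#' The defaults reproduce the final models: for piperacillin, V2 fixed at
#' 5 L, MAP priors N(20, 1) on V1pop and N(20, 3) on Qpop, age + weight on
#' V1 and renal category on Cl1; for tazobactam, V2 and Q fixed at 5 L and
#' 20 L/h, MAP prior N(20, 5) on V1pop, renal category on Cl1.
#'
#' @param drug `"PIP"` or `"TAZ"`.
#' @param estimate character vector of estimated fixed effects (subset of
#'   `V1pop`, `Qpop`, `Cl1pop`, `Cl2pop`; `V2pop` is always fixed).
#' @param fixed_values named list of values for the non-estimated fixed
#'   effects.
#' @param priors named list of MAP priors `c(mean, sd)` (natural scale).
#' @param covariates list with elements `V1` (subset of `"age"`,
#'   `"weight"`) and `Cl1` (subset of `"age"`, `"weight"`, `"catB"`,
#'   `"catC"`).
#' @param iiv parameters with inter-individual variability (subset of
#'   `"V1"`, `"Cl1"`, `"Cl2"`).
#' @param iov parameters with inter-occasion variability (`"Cl1"` or
#'   empty).
#' @param blq below-LLOQ handling: `"exclude"` (M1, flagged observations
#'   are dropped) or `"censored"` (M3, their likelihood contribution is the
#'   normal CDF at the LLOQ; removes the selection bias that exclusion
#'   induces on clearance when censoring is informative).
#' @param centered logical, covariate centering mode (see
#'   [population_params()]).
#' @param control a [saem_control()].
#' @return A list of class `fit_spec`.
#' @export
fit_spec <- function(drug = c("PIP", "TAZ"),
                     estimate = NULL,
                     fixed_values = NULL,
                     priors = NULL,
                     covariates = NULL,
                     iiv = c("V1", "Cl1", "Cl2"),
                     iov = "Cl1",
                     blq = c("exclude", "censored"),
                     centered = FALSE,
                     control = saem_control()) {
  blq <- match.arg(blq)
  drug <- match.arg(drug)
  if (drug == "PIP") {
    estimate <- estimate %||% c("V1pop", "Qpop", "Cl1pop", "Cl2pop")
    fixed_values <- fixed_values %||% list(V2pop = 5)
    priors <- priors %||% list(V1pop = c(20, 1), Qpop = c(20, 3))
    covariates <- covariates %||% list(V1 = c("age", "weight"),
                                       Cl1 = c("catB", "catC"))
  } else {
    estimate <- estimate %||% c("V1pop", "Cl1pop", "Cl2pop")
    fixed_values <- fixed_values %||% list(V2pop = 5, Qpop = 20)
    priors <- priors %||% list(V1pop = c(20, 5))
    covariates <- covariates %||% list(V1 = character(),
                                       Cl1 = c("catB", "catC"))
  }
  if ("V2pop" %in% estimate) stopf("V2pop is always fixed")
  if (is.null(fixed_values$V2pop)) stopf("fixed_values must give V2pop")
  bad <- setdiff(names(priors), estimate)
  if (length(bad))
    stopf("priors declared on non-estimated parameters: %s",
          paste(bad, collapse = ", "))
  covariates$V1 <- intersect(covariates$V1 %||% character(),
                             c("age", "weight"))
  covariates$Cl1 <- intersect(covariates$Cl1 %||% character(),
                              c("age", "weight", "catB", "catC"))
  iiv <- intersect(iiv, c("V1", "Cl1", "Cl2"))
  iov <- intersect(iov, "Cl1")
  structure(list(drug = drug, estimate = estimate,
                 fixed_values = fixed_values, priors = priors,
                 covariates = covariates, iiv = iiv, iov = iov,
                 blq = blq, centered = centered, control = control),
            class = "fit_spec")
}
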