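## simulate replicate observation vectors under the model at the dataset's
## design: new random effects + proportional noise at the observed times
simulate_from_model <- function(plan, st, spec, n_sim) {
  lat <- latent_config(spec)
  n <- plan$n
  nob <- nrow(plan$obs)
  sims <- matrix(NA_real_, nob, n_sim)
  M <- phi_means(plan, st, lat)
  bb <- ifelse(plan$obs$cmt == 1L, st$b[1], st$b[2])
  for (s in seq_len(n_sim)) {
    PHI <- M
    for (j in seq_len(nrow(lat))) {
      nm <- lat$name[j]
      if (lat$kind[j] == "plain") {
        sd <- st$omega[[nm]]
        PHI[, j] <- M[, j] + stats::rnorm(n, 0, sd)
      }
    }
    if ("Cl1.o1" %in% lat$name) {
      j1 <- match("Cl1.o1", lat$name); j2 <- match("Cl1.o2", lat$name)
      eta <- stats::rnorm(n, 0, st$omega$Cl1)
      PHI[, j1] <- M[, j1] + eta + stats::rnorm(n, 0, st$gamma)
      PHI[, j2] <- M[, j2] + eta + stats::rnorm(n, 0, st$gamma)
    }
    pars <- state_params(plan, st, PHI, lat)
    fs <- plan_predict(plan, pars$V1, pars$Q, pars$Cl1occ, pars$Cl2, pars$V2)
    sims[, s] <- pmax(fs * (1 + bb * stats::rnorm(nob)), 0)
  }
  sims
}

state_from_params <- function(pop, spec, plan) {
  st <- init_from_params(pop, plan, spec)
  st$omega <- list(V1 = pop$omegaV1, Cl1 = pop$omegaCl1, Cl2 = pop$omegaCl2)
  st$gamma <- pop$gammaCl1
  st$b <- c(pop$bC1, pop$bC2)
  st
}

#' Model diagnostics: R-squared, weighted residuals, NPDE and VPC
#'
#' Simulation-based diagnostic bundle for a converged population fit (or
#' for a [population_params()] object evaluated against a dataset, which
#' is useful for calibration checks on self-simulated data):
#' observed-vs-predicted coefficients of determination per compartment
#' (population and individual predictions), individual weighted residuals,
#' simulation-based population weighted residuals (per-subject
#' decorrelation via the Cholesky factor of the simulated covariance),
#' normalized prediction distribution errors, and a prediction-corrected
#' visual predictive check.
#'
#' @param object a `pk_fit`, or a [population_params()] object (then
#'   `dataset` and `spec` are required).
#' @param dataset long-format event table (required when `object` is not a
#'   fit).
#' @param spec a [fit_spec()] (required when `object` is not a fit).
#' @param n_sim number of model simulations; must be >= 50 for a stable
#'   NPDE.
#' @param seed integer seed.
#' @param vpc_bins number of time bins for the VPC.
#' @return A list of class `pk_diagnostics`: `r2` (per compartment,
#'   population and individual), `residuals` (per-observation table with
#'   `f_pop`, `f_ind`, `iwres`, `pwres`, `npde`), `vpc` (binned observed
#'   percentiles with simulated 95% bands), `n_sim`.
#' @export
model_diagnostics <- function(object, dataset = NULL, spec = NULL,
                              n_sim = 500, seed = 1L, vpc_bins = 6) {
  if (n_sim < 50) stopf("n_sim must be >= 50 for a stable NPDE")
  set.seed(seed)
  if (inherits(object, "pk_fit")) {
    plan <- object$plan; st <- object$state; spec <- object$spec
    phi_ind <- object$phi
  } else if (inherits(object, "population_params")) {
    if (is.null(dataset) || is.null(spec))
      stopf("'dataset' and 'spec' are required with population_params input")
    plan <- build_plan(dataset, spec)
    st <- state_from_params(object, spec, plan)
    lat0 <- latent_config(spec)
    fit0 <- structure(list(plan = plan, state = st, spec = spec,
                           lat = lat0,
                           PHI_last = phi_means(plan, st, lat0)),
                      class = "pk_fit")
    phi_ind <- ebe_laplace(fit0)$phi
  } else stopf("'object' must be a pk_fit or population_params")
  ## censored rows carry no measured value; diagnostics use observed rows
  plan$obs <- plan$obs[plan$obs$cens == 0L, , drop = FALSE]
  lat <- latent_config(spec)
  n <- plan$n; ob <- plan$obs
  M <- phi_means(plan, st, lat)
  p0 <- state_params(plan, st, M, lat)
  f_pop <- plan_predict(plan, p0$V1, p0$Q, p0$Cl1occ, p0$Cl2, p0$V2)
  pe <- state_params(plan, st, phi_ind, lat)
  f_ind <- plan_predict(plan, pe$V1, pe$Q, pe$Cl1occ, pe$Cl2, pe$V2)
  bb <- ifelse(ob$cmt == 1L, st$b[1], st$b[2])
  iwres <- (ob$y - f_ind) / (bb * pmax(f_ind, 1e-12))
  sims <- simulate_from_model(plan, st, spec, n_sim)
  pwres <- numeric(nrow(ob)); npde <- numeric(nrow(ob))
  for (i in seq_len(n)) {
    rows <- which(ob$sub == i)
    if (!length(rows)) next
    Si <- sims[rows, , drop = FALSE]
    m <- rowMeans(Si)
    V <- stats::cov(t(Si))
    U <- tryCatch(chol(V + diag(1e-10, length(rows))),
                  error = function(e) diag(sqrt(pmax(diag(V), 1e-10)),
                                           length(rows)))
    ystar <- backsolve(U, ob$y[rows] - m, transpose = TRUE)
    sstar <- backsolve(U, Si - m, transpose = TRUE)
    pwres[rows] <- ystar
    r <- rowSums(sstar < ystar)
    npde[rows] <- stats::qnorm((r + 0.5) / (n_sim + 1))
  }
  r2_of <- function(pred, cmt) {
    sel <- ob$cmt == cmt
    if (sum(sel) < 3) return(NA_real_)
    stats::cor(ob$y[sel], pred[sel])^2
  }
  r2 <- data.frame(compartment = c("plasma", "peritoneal"),
                   r2_population = c(r2_of(f_pop, 1L), r2_of(f_pop, 2L)),
                   r2_individual = c(r2_of(f_ind, 1L), r2_of(f_ind, 2L)))
  ## prediction-corrected VPC binned on time
  qs <- c(0.1, 0.5, 0.9)
  br <- unique(stats::quantile(ob$time, seq(0, 1, length.out = vpc_bins + 1)))
  bin <- cut(ob$time, br, include.lowest = TRUE)
  vpc <- do.call(rbind, lapply(split(seq_len(nrow(ob)), list(bin, ob$cmt),
                                     drop = TRUE), function(rows) {
    med_fpop <- stats::median(f_pop[rows])
    corr <- med_fpop / pmax(f_pop[rows], 1e-12)
    oq <- stats::quantile(ob$y[rows] * corr, qs)
    sq <- apply(sims[rows, , drop = FALSE] * corr, 2, stats::quantile, qs)
    lo <- apply(sq, 1, stats::quantile, 0.025)
    hi <- apply(sq, 1, stats::quantile, 0.975)
    data.frame(compartment = ifelse(ob$cmt[rows[1]] == 1L, "plasma",
                                    "peritoneal"),
               t_mid = mean(range(ob$time[rows])),
               quantile = qs, observed = unname(oq),
               sim_lower = lo, sim_upper = hi, n = length(rows))
  }))
  rownames(vpc) <- NULL
  structure(list(r2 = r2,
                 residuals = data.frame(sub = ob$sub, time = ob$time,
                                        compartment = ifelse(ob$cmt == 1L,
                                                             "plasma",
                                                             "peritoneal"),
                                        y = ob$y, f_pop = f_pop,
                                        f_ind = f_ind, iwres = iwres,
                                        pwres = pwres, npde = npde),
                 vpc = vpc, n_sim = n_sim),
            class = "pk_diagnostics")
}

#' @export
print.pk_diagnostics <- function(x, ...) {
  cat("Model diagnostics (", x$n_sim, "simulations )\n")
  print(x$r2, row.names = FALSE)
  cat(sprintf("  NPDE: mean %.3f, var %.3f, frac |npde| > 1.96 = %.3f\n",
              mean(x$residuals$npde), stats::var(x$residuals$npde),
              mean(abs(x$residuals$npde) > 1.96)))
  invisible(x)
}
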