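## ---- dataset -> fitting plan ---------------------------------------------
## The plan holds everything the vectorised predictor needs: global segment
## boundaries (all subjects' dose start/end times plus the occasion switch),
## per-subject rates per segment, covariate design matrices, and the
## observation table. The two-compartment system is advanced exactly per
## segment, so predictions are closed-form.

build_plan <- function(dataset, spec) {
  d <- dataset[dataset$DRUG == spec$drug, , drop = FALSE]
  if (!nrow(d)) stopf("no rows for drug %s", spec$drug)
  censored <- identical(spec$blq, "censored")
  keep <- d$EVID == 0 & d$MATRIX %in% c("plasma", "peritoneal") &
    d$TIME > 0 & (if (censored) d$MDV == 0 | d$BLQ == 1 else d$MDV == 0)
  obs <- d[keep, , drop = FALSE]
  cens <- censored & obs$BLQ == 1
  obs$DV[cens] <- obs$LLOQ[cens]
  ids <- sort(unique(obs$ID))
  if (length(ids) < 2) stopf("need >= 2 subjects with usable observations")
  n <- length(ids)
  idx <- match(obs$ID, ids)
  doses <- d[d$EVID == 1, , drop = FALSE]
  if (!nrow(doses)) stopf("no dose events")
  ends <- doses$TIME + doses$DUR
  t_occ <- spec$control$t_occ
  bounds <- sort(unique(c(0, doses$TIME, ends[is.finite(ends)], t_occ)))
  nseg <- length(bounds)
  R <- matrix(0, n, nseg)
  for (i in seq_len(n)) {
    di <- doses[doses$ID == ids[i], , drop = FALSE]
    de <- di$TIME + ifelse(is.na(di$DUR), Inf, di$DUR)
    for (s in seq_len(nseg))
      R[i, s] <- sum(di$RATE[di$TIME <= bounds[s] + 1e-12 &
                               de > bounds[s] + 1e-12])
  }
  occ_seg <- ifelse(bounds < t_occ, 1L, 2L)
  seg <- findInterval(obs$TIME, bounds + 1e-12) ## segment containing t
  seg[seg < 1] <- 1L
  ## subject-level covariates
  first <- match(ids, d$ID)
  age <- d$AGE[first]; wt <- d$WT[first]
  cat <- d$RENAL_CAT[first]
  cat[cat == "D"] <- "A"
  if (spec$centered) { age <- age - AGE_REF; wt <- wt - WT_REF }
  mkX <- function(terms) {
    X <- matrix(1, n, 1)
    cn <- "(Intercept)"
    for (tm in terms) {
      col <- switch(tm, age = age, weight = wt,
                    catB = as.numeric(cat == "B"),
                    catC = as.numeric(cat == "C"))
      X <- cbind(X, col); cn <- c(cn, tm)
    }
    colnames(X) <- cn
    X
  }
  XV1 <- mkX(spec$covariates$V1)
  XCl1 <- mkX(spec$covariates$Cl1)
  for (X in list(XV1, XCl1)) {
    zero <- colnames(X)[-1][colSums(abs(X[, -1, drop = FALSE])) == 0]
    if (length(zero))
      stopf("non-identifiable covariate(s) with no variation: %s",
            paste(zero, collapse = ", "))
  }
  list(n = n, ids = ids, bounds = bounds, nseg = nseg, R = R,
       occ_seg = occ_seg, dt = diff(bounds), t_occ = t_occ,
       obs = data.frame(sub = idx, time = obs$TIME, seg = seg,
                        cmt = ifelse(obs$MATRIX == "plasma", 1L, 2L),
                        y = obs$DV, cens = as.integer(cens)),
       XV1 = XV1, XCl1 = XCl1,
       age = age, wt = wt, cat = cat)
}

## exact predictions at all observation rows given individual parameters;
## Cl1occ is an n x 2 matrix (occasion-specific Cl1)
plan_predict <- function(plan, V1, Q, Cl1occ, Cl2, V2) {
  n <- plan$n
  k12 <- Q / V1; k21 <- Q / V2; k20 <- Cl2 / V2
  A1 <- numeric(n); A2 <- numeric(n)
  SA1 <- matrix(0, n, plan$nseg); SA2 <- matrix(0, n, plan$nseg)
  for (s in seq_len(plan$nseg)) {
    SA1[, s] <- A1; SA2[, s] <- A2
    if (s < plan$nseg) {
      k10 <- Cl1occ[, plan$occ_seg[s]] / V1
      st <- twocpt_step(A1, A2, k10, k12, k21, k20, plan$R[, s], plan$dt[s])
      A1 <- st$A1; A2 <- st$A2
    }
  }
  ob <- plan$obs
  i <- ob$sub; s <- ob$seg
  k10o <- Cl1occ[cbind(i, plan$occ_seg[s])] / V1[i]
  st <- twocpt_step(SA1[cbind(i, s)], SA2[cbind(i, s)], k10o,
                    k12[i], k21[i], k20[i], plan$R[cbind(i, s)],
                    ob$time - plan$bounds[s])
  ifelse(ob$cmt == 1L, st$A1 / V1[i], st$A2 / V2[i])
}

## ---- latent-variable bookkeeping -----------------------------------------
## The MCMC state is the matrix of individual log-parameters phi (one
## column per latent), the parametrization used by stochastic-EM tools for
## NLME: fixed effects are then estimated by regressing sampled phi on the
## covariate design, which keeps weakly identified random-effect
## directions from leaking into the fixed effects. Inter-occasion
## variability on Cl1 makes the two occasion columns a correlated pair
## (shared subject-level eta); eta and kappa are recovered by exact
## conditional Gaussian draws. Population parameters estimated without a
## random effect (e.g. Q for piperacillin) carry no latent column and are
## updated by a penalized conditional 1-D maximization.

latent_config <- function(spec) {
  nm <- character(); kind <- character()
  if ("V1" %in% spec$iiv) { nm <- c(nm, "V1"); kind <- c(kind, "plain") }
  if ("Cl1" %in% spec$iiv) {
    if ("Cl1" %in% spec$iov) {
      nm <- c(nm, "Cl1.o1", "Cl1.o2"); kind <- c(kind, "pair", "pair")
    } else { nm <- c(nm, "Cl1"); kind <- c(kind, "plain") }
  }
  if ("Cl2" %in% spec$iiv) { nm <- c(nm, "Cl2"); kind <- c(kind, "plain") }
  data.frame(name = nm, kind = kind, stringsAsFactors = FALSE)
}

## population parameters estimated by conditional maximization (no latent)
cond_pops <- function(spec) {
  out <- character()
  for (p in c("V1", "Q", "Cl1", "Cl2")) {
    if (paste0(p, "pop") %in% spec$estimate && !(p %in% spec$iiv))
      out <- c(out, p)
  }
  out
}

phi_col <- function(PHI, lat, name) {
  j <- match(name, lat$name)
  if (is.na(j)) NULL else PHI[, j]
}

## covariate contribution (design matrix minus its intercept column)
covpart <- function(X, beta) {
  if (length(beta)) drop(X[, -1, drop = FALSE] %*% beta) else 0
}

## mean structure of the latent columns (n x nlat)
phi_means <- function(plan, st, lat) {
  mV1 <- st$mu[["V1"]] + covpart(plan$XV1, st$betaV1)
  mCl1 <- st$mu[["Cl1"]] + covpart(plan$XCl1, st$betaCl1)
  mCl2 <- rep(st$mu[["Cl2"]], plan$n)
  M <- matrix(0, plan$n, nrow(lat))
  for (j in seq_len(nrow(lat)))
    M[, j] <- switch(sub("\\..*", "", lat$name[j]),
                     V1 = mV1, Cl1 = mCl1, Cl2 = mCl2)
  M
}

## individual structural parameters from the state and phi matrix
state_params <- function(plan, st, PHI, lat) {
  n <- plan$n
  M <- phi_means(plan, st, lat)
  getcol <- function(name, fallback) {
    v <- phi_col(PHI, lat, name)
    if (is.null(v)) fallback else exp(v)
  }
  mV1 <- rep_len(st$mu[["V1"]] + covpart(plan$XV1, st$betaV1), n)
  mCl1 <- rep_len(st$mu[["Cl1"]] + covpart(plan$XCl1, st$betaCl1), n)
  V1 <- getcol("V1", exp(mV1))
  Cl2 <- getcol("Cl2", rep(exp(st$mu[["Cl2"]]), n))
  if (!is.null(phi_col(PHI, lat, "Cl1.o1"))) {
    Cl1occ <- cbind(exp(phi_col(PHI, lat, "Cl1.o1")),
                    exp(phi_col(PHI, lat, "Cl1.o2")))
  } else {
    c1 <- getcol("Cl1", exp(mCl1))
    Cl1occ <- cbind(c1, c1)
  }
  list(V1 = V1, Q = rep(exp(st$mu[["Q"]]), n), Cl1occ = Cl1occ, Cl2 = Cl2,
       V2 = rep(st$V2, n))
}

## log prior density of the latent matrix, per subject (n-vector)
phi_logprior <- function(plan, st, PHI, lat) {
  M <- phi_means(plan, st, lat)
  lp <- numeric(plan$n)
  for (j in seq_len(nrow(lat))) {
    if (lat$name[j] == "Cl1.o2") next  ## handled jointly with o1
    if (lat$kind[j] == "plain") {
      sd <- st$omega[[lat$name[j]]]
      lp <- lp + stats::dnorm(PHI[, j], M[, j], max(sd, 1e-6), log = TRUE)
    } else {  ## bivariate occasion pair for Cl1
      j2 <- match("Cl1.o2", lat$name)
      d1 <- PHI[, j] - M[, j]; d2 <- PHI[, j2] - M[, j2]
      s <- st$omega$Cl1^2 + st$gamma^2
      r <- st$omega$Cl1^2
      det <- pmax(s^2 - r^2, 1e-12)
      q <- (s * d1^2 - 2 * r * d1 * d2 + s * d2^2) / det
      lp <- lp - 0.5 * q - 0.5 * log(4 * pi^2 * det)
    }
  }
  lp
}

## per-subject observation log-likelihood given predictions; censored rows
## contribute the normal CDF at the quantification limit; non-finite or
## non-positive predictions against positive observations get a large
## finite penalty (keeps Metropolis rejection and BFGS well-defined)
obs_loglik <- function(plan, f, b) {
  ob <- plan$obs
  bb <- ifelse(ob$cmt == 1L, b[1], b[2])
  li <- numeric(length(f))
  ok <- is.finite(f) & f > 0
  nc <- ok & ob$cens == 0L
  li[nc] <- stats::dnorm(ob$y[nc], f[nc], bb[nc] * f[nc], log = TRUE)
  cs <- ok & ob$cens == 1L
  li[cs] <- stats::pnorm(ob$y[cs], f[cs], bb[cs] * f[cs], log.p = TRUE)
  li[!ok & !(is.finite(f) & ob$y <= 0)] <- -1e10
  li[!is.finite(li)] <- -1e10
  rowsum(li, ob$sub, reorder = TRUE)[, 1]
}

## penalized least squares for one parameter group M-step
solve_group <- function(XtX, S_xz, S_zz, N, var_cur, prior) {
  p <- length(S_xz)
  coef_of_mu <- function(mu) {
    if (p > 1) c(mu, solve(XtX[-1, -1, drop = FALSE],
                           S_xz[-1] - XtX[-1, 1] * mu))
    else mu
  }
  if (is.null(prior)) {
    coef <- drop(solve(XtX, S_xz))
  } else {
    obj <- function(mu) {
      cf <- coef_of_mu(mu)
      quad <- S_zz - 2 * sum(cf * S_xz) + drop(t(cf) %*% XtX %*% cf)
      quad / (2 * var_cur) + (exp(mu) - prior[1])^2 / (2 * prior[2]^2)
    }
    mu <- stats::optimize(obj, c(-6, 8))$minimum
    coef <- coef_of_mu(mu)
  }
  resid2 <- (S_zz - 2 * sum(coef * S_xz) +
               drop(t(coef) %*% XtX %*% coef)) / N
  list(coef = coef, resid2 = max(resid2, 1e-8))
}

## ---- initial values -------------------------------------------------------

default_init <- function(plan, spec) {
  ob <- plan$obs
  mu <- c(V1 = log(20), Q = log(20), Cl1 = log(10), Cl2 = log(2))
  if (!is.null(spec$priors$V1pop)) mu["V1"] <- log(spec$priors$V1pop[1])
  if (!is.null(spec$priors$Qpop)) mu["Q"] <- log(spec$priors$Qpop[1])
  if (!is.null(spec$fixed_values$Qpop)) mu["Q"] <- log(spec$fixed_values$Qpop)
  if (!is.null(spec$fixed_values$V1pop)) mu["V1"] <- log(spec$fixed_values$V1pop)
  if (!is.null(spec$fixed_values$Cl1pop)) mu["Cl1"] <- log(spec$fixed_values$Cl1pop)
  if (!is.null(spec$fixed_values$Cl2pop)) mu["Cl2"] <- log(spec$fixed_values$Cl2pop)
  ## crude clearance init from apparent rate/Css at late plasma samples
  late <- ob$cmt == 1L & ob$time >= 24 & ob$y > 0 & ob$cens == 0L
  betaCl1 <- numeric(ncol(plan$XCl1) - 1)
  names(betaCl1) <- colnames(plan$XCl1)[-1]
  if (any(late) && "Cl1pop" %in% spec$estimate) {
    rate <- plan$R[cbind(ob$sub[late], ob$seg[late])]
    zcl <- log(pmax(rate / ob$y[late], 1e-3))
    cats <- plan$cat[ob$sub[late]]
    ref <- cats == "A"
    if (any(ref)) mu["Cl1"] <- stats::median(zcl[ref])
    for (cv in names(betaCl1)) {
      if (cv %in% c("catB", "catC")) {
        sel <- cats == sub("cat", "", cv)
        if (any(sel)) betaCl1[cv] <- stats::median(zcl[sel]) - mu["Cl1"]
      }
    }
  }
  ## crude V1 init from the end-of-load sample where no prior anchors it
  early <- ob$cmt == 1L & ob$time <= 1 & ob$y > 0
  if (any(early) && is.null(spec$priors$V1pop) &&
      "V1pop" %in% spec$estimate) {
    load_amt <- plan$R[, 1] * plan$dt[1]
    mu["V1"] <- log(stats::median(pmax(
      0.8 * load_amt[ob$sub[early]] / ob$y[early], 1)))
  }
  list(mu = mu, betaV1 = stats::setNames(numeric(ncol(plan$XV1) - 1),
                                         colnames(plan$XV1)[-1]),
       betaCl1 = betaCl1,
       omega = list(V1 = 0.3, Cl1 = 0.3, Cl2 = 0.3),
       gamma = 0.3, b = c(0.2, 0.2),
       V2 = spec$fixed_values$V2pop)
}

init_from_params <- function(pop, plan, spec) {
  st <- default_init(plan, spec)
  st$mu <- c(V1 = log(pop$V1pop), Q = log(pop$Qpop),
             Cl1 = log(pop$Cl1pop), Cl2 = log(pop$Cl2pop))
  bv <- c(age = pop$betaV1_age, weight = pop$betaV1_weight)
  st$betaV1[] <- bv[names(st$betaV1)]
  bc <- c(age = pop$betaCl1_age, weight = 0,
          catB = pop$betaCl1_catB, catC = pop$betaCl1_catC)
  st$betaCl1[] <- bc[names(st$betaCl1)]
  st$omega <- list(V1 = max(pop$omegaV1, 0.05),
                   Cl1 = max(pop$omegaCl1, 0.05),
                   Cl2 = max(pop$omegaCl2, 0.05))
  st$gamma <- max(pop$gammaCl1, 0.05)
  st$b <- c(max(pop$bC1, 0.05), max(pop$bC2, 0.05))
  st$V2 <- spec$fixed_values$V2pop
  st
}

## ---- SAEM -----------------------------------------------------------------

#' Fit the population model by SAEM
#'
#' Stochastic-approximation EM with a Metropolis-within-Gibbs E-step on the
#' individual log-parameters (vectorised across subjects), closed-form
#' M-steps on the log-parameter linear model, MAP priors applied once as
#' natural-scale penalties, variance annealing during exploration, and
#' decreasing step sizes during smoothing. Inter-occasion variability on
#' Cl1 is handled as a correlated occasion pair with exact conditional
#' decomposition into subject-level and occasion-level effects. Only
#' plasma and peritoneal observations enter the likelihood; VAC-fluid and
#' urine rows are ignored, and below-LLOQ rows are excluded or treated as
#' left-censored per the estimation specification's `blq` setting.
#'
#' @param dataset long-format event table ([cohort_to_dataset()] /
#'   [read_pk_dataset()]).
#' @param spec a [fit_spec()].
#' @param init optional [population_params()] with starting values;
#'   defaults to crude data-derived inits.
#' @return An object of class `pk_fit` with elements `params` (the
#'   estimated [population_params()]), `logLik` (Laplace marginal
#'   log-likelihood), `eta` (empirical-Bayes modes of the individual
#'   log-parameters, deviations from their mean structure), `trace`
#'   (parameter trajectory), `converged`, and `n_theta` (number of
#'   estimated fixed effects + covariate coefficients).
#' @export
fit_population <- function(dataset, spec, init = NULL) {
  if (!inherits(spec, "fit_spec")) stopf("'spec' must be a fit_spec")
  ctl <- spec$control
  if (!is.null(ctl$seed)) set.seed(ctl$seed)
  plan <- build_plan(dataset, spec)
  n <- plan$n
  st <- if (is.null(init)) default_init(plan, spec)
        else init_from_params(init, plan, spec)
  lat <- latent_config(spec)
  nlat <- nrow(lat)
  PHI <- phi_means(plan, st, lat)
  step <- rep(0.4, nlat)
  has_c2 <- any(plan$obs$cmt == 2L)
  unc <- plan$obs$cens == 0L
  n_obs_c <- c(sum(plan$obs$cmt == 1L & unc), sum(plan$obs$cmt == 2L & unc))
  pars <- state_params(plan, st, PHI, lat)
  f <- plan_predict(plan, pars$V1, pars$Q, pars$Cl1occ, pars$Cl2, pars$V2)
  ll <- obs_loglik(plan, f, st$b)
  lp <- phi_logprior(plan, st, PHI, lat)
  XtXV1 <- crossprod(plan$XV1); XtXCl1 <- crossprod(plan$XCl1)
  stats <- NULL
  n_iter <- ctl$n_burn + ctl$n_smooth
  est <- spec$estimate
  cond <- cond_pops(spec)
  iov_on <- "Cl1" %in% spec$iov && "Cl1" %in% spec$iiv
  pn <- function(prefix, v) {
    if (length(v)) paste0(prefix, names(v)) else character(0)
  }
  trace_names <- c("V1pop", "Qpop", "Cl1pop", "Cl2pop",
                   pn("bV1.", st$betaV1),
                   pn("bCl1.", st$betaCl1),
                   "omegaV1", "omegaCl1", "omegaCl2", "gammaCl1",
                   "bC1", "bC2")
  trace <- matrix(NA_real_, n_iter, length(trace_names),
                  dimnames = list(NULL, trace_names))
  for (k in seq_len(n_iter)) {
    a_k <- if (k <= ctl$n_burn) 1 else 1 / (k - ctl$n_burn)
    ## ---- E-step: Metropolis-within-Gibbs on phi columns ----
    for (pass in seq_len(ctl$mh_steps)) {
      for (j in seq_len(nlat)) {
        PHIp <- PHI
        PHIp[, j] <- PHI[, j] + stats::rnorm(n, 0, step[j])
        pp <- state_params(plan, st, PHIp, lat)
        fp <- plan_predict(plan, pp$V1, pp$Q, pp$Cl1occ, pp$Cl2, pp$V2)
        llp <- obs_loglik(plan, fp, st$b)
        lpp <- phi_logprior(plan, st, PHIp, lat)
        acc <- log(stats::runif(n)) < (llp - ll) + (lpp - lp)
        if (any(acc)) {
          PHI[acc, j] <- PHIp[acc, j]
          sel <- acc[plan$obs$sub]
          f[sel] <- fp[sel]
          ll[acc] <- llp[acc]
          lp[acc] <- lpp[acc]
        }
        if (k <= ctl$n_burn && pass == 1)
          step[j] <- min(max(step[j] * exp(0.4 * (mean(acc) - 0.35)),
                             0.02), 5)
      }
    }
    ## ---- sufficient statistics ----
    zV1 <- phi_col(PHI, lat, "V1")
    zCl2 <- phi_col(PHI, lat, "Cl2")
    if (iov_on) {
      z1 <- phi_col(PHI, lat, "Cl1.o1"); z2 <- phi_col(PHI, lat, "Cl1.o2")
      ## exact conditional decomposition phi = m + eta + kappa
      mCl1 <- st$mu[["Cl1"]] + covpart(plan$XCl1, st$betaCl1)
      d1 <- z1 - mCl1; d2 <- z2 - mCl1
      w2 <- st$omega$Cl1^2; g2 <- st$gamma^2
      mn <- w2 * (d1 + d2) / (2 * w2 + g2)
      vr <- w2 * g2 / (2 * w2 + g2)
      eta_cl1 <- stats::rnorm(n, mn, sqrt(pmax(vr, 0)))
      kap2 <- (d1 - eta_cl1)^2 + (d2 - eta_cl1)^2
    } else {
      z1 <- phi_col(PHI, lat, "Cl1")
      eta_cl1 <- NULL; kap2 <- NULL
    }
    res1 <- (plan$obs$y - f) / pmax(f, 1e-12)
    S_new <- list(
      V1_xz = if (is.null(zV1)) NULL else drop(crossprod(plan$XV1, zV1)),
      V1_zz = if (is.null(zV1)) NULL else sum(zV1^2),
      Cl2_z = if (is.null(zCl2)) NULL else sum(zCl2),
      Cl2_zz = if (is.null(zCl2)) NULL else sum(zCl2^2),
      Cl1_xz = if (is.null(z1)) NULL else if (iov_on)
        drop(crossprod(plan$XCl1, z1 + z2)) else drop(crossprod(plan$XCl1, z1)),
      Cl1_zz = if (is.null(z1)) NULL else if (iov_on)
        sum(z1^2 + z2^2) else sum(z1^2),
      Cl1_eta2 = if (iov_on) sum(eta_cl1^2) else NULL,
      Cl1_kap2 = if (iov_on) sum(kap2) else NULL,
      res = c(sum(res1[plan$obs$cmt == 1L & unc]^2),
              sum(res1[plan$obs$cmt == 2L & unc]^2)))
    if (is.null(stats)) stats <- S_new
    else stats <- Map(function(s, sn)
      if (is.null(s)) NULL else s + a_k * (sn - s), stats, S_new)
    ## ---- M-step ----
    anneal <- function(new, old) {
      if (k <= ctl$n_burn) max(new, ctl$anneal^2 * old) else new
    }
    if ("V1pop" %in% est && "V1" %in% spec$iiv) {
      g <- solve_group(XtXV1, stats$V1_xz, stats$V1_zz, n,
                       max(st$omega$V1^2, 1e-4), spec$priors$V1pop)
      st$mu["V1"] <- g$coef[1]
      if (length(g$coef) > 1) st$betaV1[] <- g$coef[-1]
      st$omega$V1 <- sqrt(anneal(g$resid2, st$omega$V1^2))
    }
    if ("Cl2pop" %in% est && "Cl2" %in% spec$iiv) {
      g <- solve_group(matrix(n, 1, 1), stats$Cl2_z, stats$Cl2_zz, n,
                       max(st$omega$Cl2^2, 1e-4), spec$priors$Cl2pop)
      st$mu["Cl2"] <- g$coef[1]
      st$omega$Cl2 <- sqrt(anneal(g$resid2, st$omega$Cl2^2))
    }
    if ("Cl1pop" %in% est && "Cl1" %in% spec$iiv) {
      Nrows <- if (iov_on) 2 * n else n
      g <- solve_group(if (iov_on) 2 * XtXCl1 else XtXCl1,
                       stats$Cl1_xz, stats$Cl1_zz, Nrows,
                       max(if (iov_on) st$omega$Cl1^2 + st$gamma^2
                           else st$omega$Cl1^2, 1e-4),
                       spec$priors$Cl1pop)
      st$mu["Cl1"] <- g$coef[1]
      if (length(g$coef) > 1) st$betaCl1[] <- g$coef[-1]
      if (iov_on) {
        st$omega$Cl1 <- sqrt(anneal(stats$Cl1_eta2 / n, st$omega$Cl1^2))
        st$gamma <- sqrt(anneal(stats$Cl1_kap2 / (2 * n), st$gamma^2))
      } else {
        st$omega$Cl1 <- sqrt(anneal(g$resid2, st$omega$Cl1^2))
      }
    }
    ## conditional 1-D updates for no-random-effect parameters
    for (cp in cond) {
      pri <- spec$priors[[paste0(cp, "pop")]]
      obj <- function(m) {
        s2 <- st; s2$mu[cp] <- m
        pc <- state_params(plan, s2, PHI, lat)
        lo <- sum(obs_loglik(plan,
                             plan_predict(plan, pc$V1, pc$Q, pc$Cl1occ,
                                          pc$Cl2, pc$V2), st$b))
        pen <- if (is.null(pri)) 0 else (exp(m) - pri[1])^2 / (2 * pri[2]^2)
        -lo + pen
      }
      o <- stats::optimize(obj, st$mu[[cp]] + c(-1, 1))
      st$mu[cp] <- st$mu[[cp]] + min(a_k, 1) * (o$minimum - st$mu[[cp]])
    }
    st$b[1] <- sqrt(anneal(max(stats$res[1] / max(n_obs_c[1], 1), 1e-6),
                           st$b[1]^2))
    if (has_c2)
      st$b[2] <- sqrt(anneal(max(stats$res[2] / max(n_obs_c[2], 1), 1e-6),
                             st$b[2]^2))
    ## refresh cached quantities under the new parameters
    pars <- state_params(plan, st, PHI, lat)
    f <- plan_predict(plan, pars$V1, pars$Q, pars$Cl1occ, pars$Cl2, pars$V2)
    ll <- obs_loglik(plan, f, st$b)
    lp <- phi_logprior(plan, st, PHI, lat)
    trace[k, ] <- c(exp(st$mu[["V1"]]), exp(st$mu[["Q"]]),
                    exp(st$mu[["Cl1"]]), exp(st$mu[["Cl2"]]),
                    st$betaV1, st$betaCl1,
                    st$omega$V1, st$omega$Cl1, st$omega$Cl2, st$gamma,
                    st$b[1], st$b[2])
  }
  params <- state_to_params(st, spec)
  fit <- structure(list(params = params, spec = spec, plan = plan,
                        state = st, lat = lat, PHI_last = PHI,
                        trace = trace,
                        n_theta = length(est) +
                          length(spec$covariates$V1) +
                          length(spec$covariates$Cl1),
                        converged = all(is.finite(trace[n_iter, ]))),
                   class = "pk_fit")
  eb <- ebe_laplace(fit)
  fit$eta <- eb$eta
  fit$phi <- eb$phi
  fit$logLik <- eb$logLik
  fit
}

state_to_params <- function(st, spec) {
  bv <- st$betaV1; bc <- st$betaCl1
  ## fixed parameters are reported exactly as declared (no exp(log(x))
  ## round trip)
  popval <- function(name, key) {
    if (name %in% spec$estimate || is.null(spec$fixed_values[[name]]))
      exp(st$mu[[key]])
    else spec$fixed_values[[name]]
  }
  population_params(spec$drug,
                    V1pop = popval("V1pop", "V1"), V2pop = st$V2,
                    Qpop = popval("Qpop", "Q"),
                    Cl1pop = popval("Cl1pop", "Cl1"),
                    Cl2pop = popval("Cl2pop", "Cl2"),
                    betaV1_age = if ("age" %in% names(bv)) bv[["age"]] else 0,
                    betaV1_weight = if ("weight" %in% names(bv)) bv[["weight"]] else 0,
                    betaCl1_age = if ("age" %in% names(bc)) bc[["age"]] else 0,
                    betaCl1_catB = if ("catB" %in% names(bc)) bc[["catB"]] else 0,
                    betaCl1_catC = if ("catC" %in% names(bc)) bc[["catC"]] else 0,
                    omegaV1 = if ("V1" %in% spec$iiv) st$omega$V1 else 0,
                    omegaCl1 = if ("Cl1" %in% spec$iiv) st$omega$Cl1 else 0,
                    omegaCl2 = if ("Cl2" %in% spec$iiv) st$omega$Cl2 else 0,
                    gammaCl1 = if ("Cl1" %in% spec$iov) st$gamma else 0,
                    bC1 = st$b[1], bC2 = st$b[2],
                    fixed = setdiff(c("V1pop", "V2pop", "Qpop",
                                      "Cl1pop", "Cl2pop"),
                                    spec$estimate),
                    priors = spec$priors,
                    centered = spec$centered)
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("Population fit (%s), %d subjects, %d observations\n",
              x$spec$drug, x$plan$n, nrow(x$plan$obs)))
  cat(sprintf("  Laplace log-likelihood: %.2f\n", x$logLik))
  print(x$params)
  invisible(x)
}

#' @export
logLik.pk_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_theta, class = "logLik")
}

## ---- empirical Bayes modes + Laplace marginal likelihood ------------------

subject_negloglik <- function(fit, i, phi) {
  plan <- fit$plan; st <- fit$state; lat <- fit$lat
  sel <- plan$obs$sub == i
  sub <- list(n = 1L, bounds = plan$bounds, nseg = plan$nseg,
              R = plan$R[i, , drop = FALSE], occ_seg = plan$occ_seg,
              dt = plan$dt,
              obs = data.frame(sub = 1L, time = plan$obs$time[sel],
                               seg = plan$obs$seg[sel],
                               cmt = plan$obs$cmt[sel],
                               y = plan$obs$y[sel],
                               cens = plan$obs$cens[sel]),
              XV1 = plan$XV1[i, , drop = FALSE],
              XCl1 = plan$XCl1[i, , drop = FALSE])
  P1 <- matrix(phi, 1)
  pars <- state_params(sub, st, P1, lat)
  ff <- plan_predict(sub, pars$V1, pars$Q, pars$Cl1occ, pars$Cl2, pars$V2)
  lo <- obs_loglik(sub, ff, st$b)
  -(lo + phi_logprior(sub, st, P1, lat))
}

ebe_laplace <- function(fit) {
  plan <- fit$plan; lat <- fit$lat
  nlat <- nrow(lat)
  phi <- matrix(0, plan$n, max(nlat, 1),
                dimnames = list(NULL, if (nlat) lat$name else "none"))
  logL <- 0
  M <- phi_means(plan, fit$state, lat)
  for (i in seq_len(plan$n)) {
    f <- function(p) subject_negloglik(fit, i, p)
    if (nlat == 0) { logL <- logL - f(numeric(0)); next }
    o <- stats::optim(fit$PHI_last[i, seq_len(nlat)], f, method = "BFGS",
                      control = list(maxit = 200))
    phi[i, ] <- o$par
    H <- stats::optimHess(o$par, f)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    ldet <- sum(log(pmax(ev, 1e-10)))
    logL <- logL - o$value + 0.5 * nlat * log(2 * pi) - 0.5 * ldet
  }
  list(phi = phi, eta = phi - M, logLik = logL)
}

## ---- likelihood ratio test ------------------------------------------------

#' Likelihood-ratio comparison of nested fits
#'
#' Chi-square test on twice the marginal log-likelihood difference; the
#' covariate-inclusion rule of the analysis is p < 0.05.
#'
#' @param nested,full `pk_fit` objects, `nested` a restriction of `full`.
#' @param df degrees of freedom; default is the difference in the number
#'   of estimated fixed effects and covariate coefficients.
#' @return A list with `statistic` (2 * delta logLik), `df` and `p_value`.
#' @export
lrt_compare <- function(nested, full, df = NULL) {
  stat <- 2 * (full$logLik - nested$logLik)
  df <- df %||% (full$n_theta - nested$n_theta)
  if (df < 1) stopf("'full' must estimate more parameters than 'nested'")
  if (stat < -1e-6)
    warnf("full model has lower log-likelihood than nested (delta = %.3g); possible convergence failure",
          stat / 2)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(max(stat, 0), df, lower.tail = FALSE))
}

## ---- bootstrap -------------------------------------------------------------

#' Bootstrap confidence intervals for population parameters
#'
#' Nonparametric bootstrap resampling subjects with replacement, refitting
#' each replicate, and reporting 2.5/97.5 percentile intervals.
#' Non-convergent replicates are excluded and counted.
#'
#' @param dataset long-format event table.
#' @param spec a [fit_spec()].
#' @param init optional starting [population_params()].
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed driving the resampling and each replicate fit.
#' @return A list with `ci` (data frame: parameter, lower, upper, median),
#'   `estimates` (replicate-by-parameter matrix) and `n_failed`.
#' @export
bootstrap_ci <- function(dataset, spec, init = NULL, n_reps = 1000,
                         seed = 1L) {
  set.seed(seed)
  ids <- unique(dataset$ID[dataset$EVID == 0 & dataset$DRUG == spec$drug])
  draws <- matrix(sample(ids, n_reps * length(ids), replace = TRUE),
                  nrow = n_reps)
  rep_seeds <- sample.int(2^31 - 2, n_reps)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    pieces <- lapply(seq_along(draws[r, ]), function(j) {
      dd <- dataset[dataset$ID == draws[r, j], , drop = FALSE]
      dd$ID <- j
      dd
    })
    bd <- do.call(rbind, pieces)
    spec_r <- spec
    spec_r$control$seed <- rep_seeds[r]
    out[[r]] <- tryCatch({
      ft <- fit_population(bd, spec_r, init = init)
      p <- ft$params
      c(V1pop = p$V1pop, Qpop = p$Qpop, Cl1pop = p$Cl1pop,
        Cl2pop = p$Cl2pop, betaV1_age = p$betaV1_age,
        betaV1_weight = p$betaV1_weight, betaCl1_catB = p$betaCl1_catB,
        betaCl1_catC = p$betaCl1_catC, omegaV1 = p$omegaV1,
        omegaCl1 = p$omegaCl1, omegaCl2 = p$omegaCl2,
        gammaCl1 = p$gammaCl1, bC1 = p$bC1, bC2 = p$bC2)
    }, error = function(e) NULL)
  }
  ok <- !vapply(out, is.null, logical(1))
  est <- do.call(rbind, out[ok])
  ci <- data.frame(parameter = colnames(est),
                   lower = apply(est, 2, stats::quantile, 0.025),
                   median = apply(est, 2, stats::quantile, 0.5),
                   upper = apply(est, 2, stats::quantile, 0.975),
                   row.names = NULL)
  list(ci = ci, estimates = est, n_failed = sum(!ok))
}
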