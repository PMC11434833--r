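#' Cohort design for the synthetic study emulation
#'
#' Describes the study design used to generate virtual cohorts: renal-group
#' mix, covariate distributions (normal approximations matched to the
#' cohort medians and interquartile ranges, sigma = IQR/1.349, truncated),
#' the sparse two-occasion sampling scheme (a plasma sample at the end of
#' the 30-min load, then plasma + peritoneal samples at a T1 drawn between
#' 48 and 72 h), daily drainage/urine volumes, assay quantification limits
#' and the VAC capture fraction.
#'
#' @param n_patients number of virtual patients, >= 1.
#' @param p_renal named probabilities for renal groups A/B/C/D (sum to 1).
#' @param age_median,age_iqr,age_range age distribution controls (years).
#' @param weight_median,weight_iqr,weight_range weight controls (kg).
#' @param t1_range uniform range for the T1 sampling time (h).
#' @param vac_daily_range,urine_daily_range uniform ranges for daily VAC
#'   exudate and urine volumes (L/day).
#' @param lloq named lower limits of quantification (mg/L) per drug.
#' @param f_vac VAC capture fraction in (0, 1]: the proportion of drug
#'   leaving the peritoneal compartment that is recovered in the canister
#'   fluid. 1 is model-faithful; ~0.13 reproduces the much smaller
#'   calculated VAC clearances observed clinically (capture loss).
#' @param t_occ time (h) at which the second occasion starts, default 24.
#' @param rich_times optional list with elements `plasma` and `peritoneal`:
#'   extra sampling times (h) for rich-design simulation studies.
#' @param pre_dose_trough logical; add a pre-load trough observation for
#'   patients notionally already on treatment (off by default).
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_patients = 45,
                          p_renal = c(A = 22, B = 12, C = 8, D = 3) / 45,
                          age_median = 66, age_iqr = c(57, 72),
                          age_range = c(18, 95),
                          weight_median = 83, weight_iqr = c(71, 92),
                          weight_range = c(40, 160),
                          t1_range = c(48, 72),
                          vac_daily_range = c(1, 3),
                          urine_daily_range = c(1, 4),
                          lloq = c(PIP = 0.5, TAZ = 1.5),
                          f_vac = 1,
                          t_occ = 24,
                          rich_times = NULL,
                          pre_dose_trough = FALSE) {
  if (n_patients < 1) stopf("'n_patients' must be >= 1")
  if (abs(sum(p_renal) - 1) > 1e-9) stopf("renal probabilities must sum to 1")
  if (f_vac <= 0 || f_vac > 1) stopf("'f_vac' must lie in (0, 1]")
  structure(list(n_patients = as.integer(n_patients), p_renal = p_renal,
                 age_median = age_median, age_iqr = age_iqr,
                 age_range = age_range,
                 weight_median = weight_median, weight_iqr = weight_iqr,
                 weight_range = weight_range,
                 t1_range = t1_range,
                 vac_daily_range = vac_daily_range,
                 urine_daily_range = urine_daily_range,
                 lloq = lloq, f_vac = f_vac, t_occ = t_occ,
                 rich_times = rich_times,
                 pre_dose_trough = pre_dose_trough),
            class = "cohort_design")
}

## truncated-normal draw matched to median/IQR
rtnorm_iqr <- function(n, med, iqr, range) {
  sd <- diff(iqr) / (2 * stats::qnorm(0.75))
  x <- stats::rnorm(n, med, sd)
  while (any(x < range[1] | x > range[2])) {
    bad <- x < range[1] | x > range[2]
    x[bad] <- stats::rnorm(sum(bad), med, sd)
  }
  x
}

## regimen (PIP g/day, TAZ g/day) by renal category
regimen_for_category <- function(cat) {
  switch(cat,
         A = c(PIP = 16000, TAZ = 2000),
         B = c(PIP = 16000, TAZ = 2000),
         C = c(PIP = 12000, TAZ = 1500),
         D = c(PIP = 20000, TAZ = 2500),
         stopf("unknown renal category '%s'", cat))
}

## loading amounts (mg), shared by all regimens
LOAD_MG <- c(PIP = 4000, TAZ = 500)

#' Generate a synthetic cohort
#'
#' Draws covariates and regimens per the study design, simulates true
#' two-compartment profiles (with inter-occasion Cl1 variability switching
#' at `design$t_occ`), and produces multi-matrix observations: plasma at
#' the end of the load (T0), plasma and peritoneal fluid at T1, plus
#' cumulative-collection VAC-fluid and urine concentrations over the
#' T0--T1 interval. Proportional residual error is applied to
#' concentration measurements and values below the LLOQ are flagged.
#'
#' @param design a [cohort_design()].
#' @param pop_pip,pop_taz [population_params()] objects for the two drugs.
#' @param seed integer seed; the cohort is fully reproducible given the
#'   seed.
#' @return An object of class `pk_cohort`: list with `subjects` (one row
#'   per patient), `events` (long-format event table, see
#'   [cohort_to_dataset()]), `truth` (per-drug true individual parameters
#'   and random effects) and the inputs.
#' @export
generate_cohort <- function(design = cohort_design(),
                            pop_pip = pip_reference_params(),
                            pop_taz = taz_reference_params(),
                            seed = 1L) {
  set.seed(seed)
  n <- design$n_patients
  cats <- sample(names(design$p_renal), n, replace = TRUE,
                 prob = design$p_renal)
  age <- rtnorm_iqr(n, design$age_median, design$age_iqr, design$age_range)
  wt <- rtnorm_iqr(n, design$weight_median, design$weight_iqr,
                   design$weight_range)
  t1 <- stats::runif(n, design$t1_range[1], design$t1_range[2])
  vac_daily <- stats::runif(n, design$vac_daily_range[1], design$vac_daily_range[2])
  uri_daily <- stats::runif(n, design$urine_daily_range[1], design$urine_daily_range[2])
  if (any(vac_daily <= 0) || any(uri_daily <= 0))
    stopf("fluid volumes must be strictly positive")
  subjects <- data.frame(id = seq_len(n), age = age, weight = wt,
                         renal_cat = cats, t1 = t1,
                         vac_daily = vac_daily, urine_daily = uri_daily)
  pops <- list(PIP = pop_pip, TAZ = pop_taz)
  truth <- list()
  rows <- list()
  for (drug in c("PIP", "TAZ")) {
    pop <- pops[[drug]]
    etas <- sample_random_effects(pop, n, n_occasions = 2)
    tr <- vector("list", n)
    for (i in seq_len(n)) {
      daily <- regimen_for_category(cats[i])[[drug]]
      sched <- regimen_schedule(LOAD_MG[[drug]], daily)
      cov <- covariate_vector(age[i], wt[i], cats[i])
      ## observation times
      obs <- data.frame(time = c(0.5, t1[i], t1[i]),
                        matrix = c("plasma", "plasma", "peritoneal"),
                        stringsAsFactors = FALSE)
      if (!is.null(design$rich_times)) {
        ex <- design$rich_times
        if (length(ex$plasma))
          obs <- rbind(obs, data.frame(time = ex$plasma, matrix = "plasma"))
        if (length(ex$peritoneal))
          obs <- rbind(obs, data.frame(time = ex$peritoneal,
                                       matrix = "peritoneal"))
      }
      if (isTRUE(design$pre_dose_trough))
        obs <- rbind(data.frame(time = 0, matrix = "plasma"), obs)
      obs <- obs[order(obs$time, obs$matrix), ]
      pr <- sim_occasions(pop, cov, etas[[i]], sched, obs$time, design$t_occ)
      true_c <- ifelse(obs$matrix == "plasma", pr$C1, pr$C2)
      b <- ifelse(obs$matrix == "plasma", pop$bC1, pop$bC2)
      y <- suppressWarnings(pmax(true_c * (1 + b * stats::rnorm(nrow(obs))), 0))
      ## cumulative collections over [0.5, t1]: exact closed-form integrals
      ## of the compartment amounts; amount excreted = k10*int A1 (urine)
      ## and k20*int A2 (VAC), with the Cl1 occasion switch at t_occ
      cv1 <- cov; cv1$occasion <- 1L
      cv2 <- cov; cv2$occasion <- 2L
      p1 <- individual_params(pop, cv1, etas[[i]])
      p2 <- individual_params(pop, cv2, etas[[i]])
      cl1_occ <- c(p1$Cl1, p2$Cl1)
      cl2_i <- p1$Cl2
      k1 <- rate_constants(p1); k2 <- rate_constants(p2)
      rate_cont <- daily / 24
      s0 <- twocpt_step(0, 0, k1[["k10"]], k1[["k12"]], k1[["k21"]],
                        k1[["k20"]], LOAD_MG[[drug]] / 0.5, 0.5)
      amt_uri <- 0; amt_vac <- 0
      state <- s0
      t_a <- 0.5
      if (t1[i] > design$t_occ && design$t_occ > t_a) {
        sA <- twocpt_step_integral(state$A1, state$A2, k1[["k10"]],
                                   k1[["k12"]], k1[["k21"]], k1[["k20"]],
                                   rate_cont, design$t_occ - t_a)
        amt_uri <- amt_uri + k1[["k10"]] * sA$I1
        amt_vac <- amt_vac + k1[["k20"]] * sA$I2
        state <- sA; t_a <- design$t_occ
        k_end <- k2
      } else k_end <- k1
      sB <- twocpt_step_integral(state$A1, state$A2, k_end[["k10"]],
                                 k_end[["k12"]], k_end[["k21"]],
                                 k_end[["k20"]], rate_cont, t1[i] - t_a)
      amt_uri <- amt_uri + k_end[["k10"]] * sB$I1
      amt_vac <- amt_vac + k_end[["k20"]] * sB$I2
      amt_vac <- design$f_vac * amt_vac
      dur <- t1[i] - 0.5
      v_uri <- uri_daily[i] * dur / 24
      v_vac <- vac_daily[i] * dur / 24
      c_uri <- suppressWarnings(max((amt_uri / v_uri) * (1 + pop$bC1 * stats::rnorm(1)), 0))
      c_vac <- suppressWarnings(max((amt_vac / v_vac) * (1 + pop$bC2 * stats::rnorm(1)), 0))
      lloq <- design$lloq[[drug]]
      occ_of <- function(t) ifelse(t < design$t_occ, 1L, 2L)
      o <- data.frame(ID = i, TIME = obs$time, DRUG = drug, EVID = 0L,
                      AMT = NA_real_, RATE = NA_real_, DUR = NA_real_,
                      DV = y, MDV = as.integer(y < lloq),
                      MATRIX = obs$matrix,
                      CMT = ifelse(obs$matrix == "plasma", 1L, 2L),
                      OCC = occ_of(obs$time),
                      BLQ = as.integer(y < lloq), LLOQ = lloq)
      fl <- data.frame(ID = i, TIME = t1[i], DRUG = drug, EVID = 0L,
                       AMT = NA_real_, RATE = NA_real_, DUR = NA_real_,
                       DV = c(c_uri, c_vac), MDV = 1L,
                       MATRIX = c("urine", "vac_fluid"),
                       CMT = c(3L, 4L), OCC = 2L, BLQ = 0L, LLOQ = lloq)
      d <- data.frame(ID = i, TIME = c(0, 0.5), DRUG = drug, EVID = 1L,
                      AMT = c(LOAD_MG[[drug]], NA_real_),
                      RATE = c(LOAD_MG[[drug]] / 0.5, daily / 24),
                      DUR = c(0.5, NA_real_),
                      DV = NA_real_, MDV = 1L, MATRIX = "dose", CMT = 1L,
                      OCC = 1L, BLQ = 0L, LLOQ = lloq)
      rows[[length(rows) + 1]] <- rbind(d, o, fl)
      tr[[i]] <- list(eta = etas[[i]], cl1_occ = cl1_occ,
                      params_occ2 = individual_params(pop, cv2, etas[[i]]),
                      true_conc = data.frame(time = obs$time,
                                             matrix = obs$matrix,
                                             conc = true_c),
                      amt_uri = amt_uri, amt_vac = amt_vac,
                      v_uri = v_uri, v_vac = v_vac)
    }
    truth[[drug]] <- tr
  }
  events <- do.call(rbind, rows)
  events <- events[order(events$DRUG, events$ID, events$TIME, events$EVID), ]
  rownames(events) <- NULL
  ## covariate columns
  events$AGE <- subjects$age[events$ID]
  events$WT <- subjects$weight[events$ID]
  events$RENAL_CAT <- subjects$renal_cat[events$ID]
  structure(list(subjects = subjects, events = events, truth = truth,
                 design = design, pop_pip = pop_pip, pop_taz = pop_taz,
                 seed = seed),
            class = "pk_cohort")
}

#' @export
print.pk_cohort <- function(x, ...) {
  cat(sprintf("Synthetic PK cohort: %d subjects, %d event rows (seed %d)\n",
              nrow(x$subjects), nrow(x$events), x$seed))
  print(table(x$subjects$renal_cat))
  invisible(x)
}

#' Long-format event table of a cohort
#'
#' Returns the NONMEM-like long-format dataset: one row per dose or
#' observation event with columns `ID, TIME, DRUG, EVID, AMT, RATE, DUR,
#' DV, MDV, MATRIX, CMT, OCC, BLQ, LLOQ, AGE, WT, RENAL_CAT`. `EVID` 1 =
#' dose, 0 = observation; the continuous infusion row has `DUR = NA`
#' (open-ended); `BLQ` flags values below the LLOQ (excluded from fitting
#' by default, `MDV = 1`).
#'
#' @param cohort a [generate_cohort()] result.
#' @return A data frame.
#' @export
cohort_to_dataset <- function(cohort) {
  if (!inherits(cohort, "pk_cohort")) stopf("'cohort' must be a pk_cohort")
  cohort$events
}

#' Write / read the long-format dataset
#'
#' Plain UTF-8 CSV with '.' decimal separator; `read_pk_dataset` validates
#' the schema and reports offending rows.
#'
#' @param dataset a data frame as returned by [cohort_to_dataset()].
#' @param path file path.
#' @return `read_pk_dataset` returns the validated data frame.
#' @export
write_pk_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_pk_dataset
#' @export
read_pk_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("ID", "TIME", "DRUG", "EVID", "AMT", "RATE", "DUR", "DV", "MDV",
            "MATRIX", "CMT", "OCC", "BLQ", "LLOQ", "AGE", "WT", "RENAL_CAT")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("dataset missing columns: %s",
                          paste(miss, collapse = ", "))
  bad <- which(!(d$EVID %in% c(0L, 1L)))
  if (length(bad)) stopf("invalid EVID at rows: %s",
                         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(d$EVID == 0 & !(d$MATRIX %in% c("plasma", "peritoneal",
                                               "urine", "vac_fluid")))
  if (length(bad)) stopf("invalid MATRIX at rows: %s",
                         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(d$EVID == 0 & (!is.finite(d$DV) | d$DV < 0))
  if (length(bad)) stopf("negative or missing DV at rows: %s",
                         paste(utils::head(bad, 10), collapse = ", "))
  d
}
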