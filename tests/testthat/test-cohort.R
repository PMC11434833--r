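test_that("cohort generation is reproducible and follows the design", {
  des <- cohort_design(n_patients = 45)
  c1 <- generate_cohort(des, seed = 7)
  c2 <- generate_cohort(des, seed = 7)
  expect_identical(c1, c2)
  expect_equal(nrow(c1$subjects), 45)
  ## expected renal mix 22/12/8/3 out of 45 (multinomial mean); with one
  ## draw just check all groups appear and A dominates
  tab <- table(factor(c1$subjects$renal_cat, levels = c("A", "B", "C", "D")))
  expect_true(all(tab > 0))
  expect_equal(unname(which.max(tab)), 1L)
  ## larger cohorts concentrate near the design probabilities
  big <- generate_cohort(cohort_design(n_patients = 500), seed = 8)
  frac <- as.numeric(table(factor(big$subjects$renal_cat,
                                  levels = c("A", "B", "C", "D"))) / 500)
  expect_equal(frac, c(22, 12, 8, 3) / 45, tolerance = 0.25)
  ## covariates within the truncation bounds, T1 in [48, 72]
  expect_true(all(c1$subjects$age >= 18 & c1$subjects$age <= 95))
  expect_true(all(c1$subjects$t1 >= 48 & c1$subjects$t1 <= 72))
  ## per subject and drug: two dose rows and >= 3 concentration rows
  ev <- c1$events
  for (id in c(3, 17)) {
    d <- ev[ev$ID == id & ev$DRUG == "PIP", ]
    expect_equal(sum(d$EVID == 1), 2)
    expect_gte(sum(d$EVID == 0 & d$MATRIX %in% c("plasma", "peritoneal")), 3)
    expect_equal(sum(d$MATRIX == "urine"), 1)
    expect_equal(sum(d$MATRIX == "vac_fluid"), 1)
  }
})

test_that("noise-free cohort reproduces closed-form steady state at T1", {
  pip0 <- noiseless(pip_pop)
  taz0 <- noiseless(taz_pop)
  ## T1 far enough out that even the slowest clearance category (CRRT,
  ## small Cl1) has fully equilibrated
  coh <- generate_cohort(cohort_design(n_patients = 30,
                                       t1_range = c(400, 450)),
                         pip0, taz0, seed = 3)
  ev <- coh$events
  for (drug in c("PIP", "TAZ")) {
    pop <- if (drug == "PIP") pip0 else taz0
    for (id in coh$subjects$id) {
      s <- coh$subjects[id, ]
      daily <- switch(s$renal_cat, A = , B = c(PIP = 16000, TAZ = 2000),
                      C = c(PIP = 12000, TAZ = 1500),
                      D = c(PIP = 20000, TAZ = 2500))[[drug]]
      p <- individual_params(pop, covariate_vector(s$age, s$weight,
                                                   s$renal_cat))
      ss <- steady_state(p, daily / 24)
      o <- ev[ev$ID == id & ev$DRUG == drug & ev$EVID == 0, ]
      t1pl <- o$DV[o$MATRIX == "plasma" & o$TIME > 1]
      t1pt <- o$DV[o$MATRIX == "peritoneal"]
      expect_equal(t1pl, unname(ss["C1ss"]), tolerance = 1e-6)
      expect_equal(t1pt, unname(ss["C2ss"]), tolerance = 1e-6)
    }
  }
})

test_that("steady-state collections recover the generating clearances", {
  ## f_vac = 1, no noise: the ratio-based clearance formula applied to the
  ## generated urine recovers Cl1, and to the VAC fluid recovers
  ## Cl2 * Q / (Q + Cl2)
  pip0 <- noiseless(pip_pop)
  taz0 <- noiseless(taz_pop)
  ## long T1 so the collection interval is dominated by steady state (the
  ## identity is exact only once the loading transient is negligible)
  coh <- generate_cohort(cohort_design(n_patients = 25, f_vac = 1,
                                       t1_range = c(120, 144)),
                         pip0, taz0, seed = 5)
  ex <- exposure_summary(coh, "PIP")
  per <- ex$per_subject
  for (i in seq_len(nrow(per))) {
    s <- coh$subjects[per$id[i], ]
    p <- individual_params(pip0, covariate_vector(s$age, s$weight,
                                                  s$renal_cat))
    ## occasion-2 clearance equals occasion-1 here (no IOV)
    expect_equal(per$cl_urine[i], p$Cl1, tolerance = 0.05)
    expect_equal(per$cl_vac[i], p$Cl2 * p$Q / (p$Q + p$Cl2),
                 tolerance = 0.05)
  }
})

test_that("dataset round-trips through CSV and validates schema", {
  coh <- generate_cohort(cohort_design(n_patients = 6), seed = 2)
  dat <- cohort_to_dataset(coh)
  path <- tempfile(fileext = ".csv")
  write_pk_dataset(dat, path)
  back <- read_pk_dataset(path)
  expect_equal(back$DV, dat$DV, tolerance = 1e-12)
  expect_identical(back$MATRIX, dat$MATRIX)
  expect_identical(back$ID, dat$ID)
  ## header-only write/read of an empty selection
  path2 <- tempfile(fileext = ".csv")
  write_pk_dataset(dat[0, ], path2)
  expect_equal(nrow(read_pk_dataset(path2)), 0)
  ## schema violations are rejected with row positions
  bad <- dat; bad$EVID[3] <- 7
  path3 <- tempfile(fileext = ".csv")
  write_pk_dataset(bad, path3)
  expect_error(read_pk_dataset(path3), "EVID")
  bad2 <- dat[, setdiff(names(dat), "OCC")]
  write_pk_dataset(bad2, path3)
  expect_error(read_pk_dataset(path3), "missing columns")
})

test_that("BLQ flagging responds to the quantification limit", {
  lo <- generate_cohort(cohort_design(n_patients = 40,
                                      lloq = c(PIP = 0.5, TAZ = 1.5)),
                        seed = 9)
  hi <- generate_cohort(cohort_design(n_patients = 40,
                                      lloq = c(PIP = 8, TAZ = 8)),
                        seed = 9)
  n_lo <- sum(lo$events$BLQ[lo$events$EVID == 0])
  n_hi <- sum(hi$events$BLQ[hi$events$EVID == 0])
  expect_gte(n_hi, n_lo)
  expect_gt(n_hi, 0)
})
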