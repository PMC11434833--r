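#' Fluid collection record
#'
#' One cumulative urine or VAC-canister collection between the two
#' sampling occasions, with the steady-state serum concentration used as
#' the reference.
#'
#' @param matrix `"urine"` or `"vac_fluid"`.
#' @param volume collected volume (L), > 0.
#' @param conc measured drug concentration in the fluid (mg/L), >= 0.
#' @param duration collection interval (h), > 0.
#' @param css_serum steady-state serum concentration (mg/L), >= 0.
#' @return An object of class `fluid_collection`.
#' @export
fluid_collection <- function(matrix = c("urine", "vac_fluid"), volume, conc,
                             duration, css_serum) {
  matrix <- match.arg(matrix)
  assert_num(volume, "volume", positive = TRUE, len = 1)
  assert_num(conc, "conc", nonneg = TRUE, len = 1)
  assert_num(duration, "duration", positive = TRUE, len = 1)
  assert_num(css_serum, "css_serum", nonneg = TRUE, len = 1)
  structure(list(matrix = matrix, volume = volume, conc = conc,
                 duration = duration, css_serum = css_serum),
            class = "fluid_collection")
}

#' Calculated urinary or VAC clearance
#'
#' Ratio-based clearance from a cumulative fluid collection:
#' `CL = (volume x fluid concentration) / (steady-state serum
#' concentration x interval)`, in L/h. At steady state this recovers the
#' renal clearance (urine) or `Cl2 * Q/(Q + Cl2)` (VAC fluid, with full
#' capture).
#'
#' @param fc a [fluid_collection()].
#' @return Clearance in L/h.
#' @examples
#' calculated_clearance(fluid_collection("vac_fluid", 1.2, 600, 24, 50))
#' @export
calculated_clearance <- function(fc) {
  if (!inherits(fc, "fluid_collection")) stopf("'fc' must be a fluid_collection")
  if (fc$css_serum <= 0)
    stopf("undefined clearance: steady-state serum concentration is zero")
  (fc$volume * fc$conc) / (fc$css_serum * fc$duration)
}

#' Peritoneal diffusion ratio
#'
#' Percent ratio of unbound peritoneal to plasma concentration at steady
#' state.
#'
#' @param peritoneal,plasma concentrations (mg/L); `plasma` must be > 0.
#' @return Percentage.
#' @export
diffusion_ratio <- function(peritoneal, plasma) {
  assert_num(peritoneal, "peritoneal", nonneg = TRUE)
  assert_num(plasma, "plasma")
  if (any(plasma <= 0)) stopf("undefined ratio: plasma concentration is zero")
  100 * peritoneal / plasma
}

#' Classify underdosing at the peritoneal site
#'
#' Strict-inequality classification of a peritoneal unbound steady-state
#' concentration against the empirical underdosing thresholds: 16 mg/L for
#' piperacillin; for tazobactam both reported thresholds are available,
#' 2 mg/L (default) and the worst-case 4 mg/L.
#'
#' @param drug `"PIP"` or `"TAZ"`.
#' @param peritoneal_css peritoneal unbound concentration (mg/L), >= 0.
#' @param taz_threshold tazobactam threshold, 2 (default) or 4 mg/L.
#' @return Logical: `TRUE` if underdosed (concentration strictly below the
#'   threshold).
#' @export
classify_underdosing <- function(drug = c("PIP", "TAZ"), peritoneal_css,
                                 taz_threshold = 2) {
  drug <- match.arg(drug)
  assert_num(peritoneal_css, "peritoneal_css", nonneg = TRUE)
  if (!taz_threshold %in% c(2, 4))
    stopf("'taz_threshold' must be 2 or 4 mg/L")
  thr <- if (drug == "PIP") 16 else taz_threshold
  peritoneal_css < thr
}

#' Cohort-level exposure summary
#'
#' Applies the non-compartmental metrics to a generated cohort: per
#' subject, the T1 plasma concentration is taken as the steady-state serum
#' reference, the peritoneal diffusion ratio is computed from the T1
#' peritoneal/plasma pair, calculated clearances from the cumulative urine
#' and VAC collections, and underdosing is classified from the peritoneal
#' concentration.
#'
#' @param cohort a [generate_cohort()] result.
#' @param drug `"PIP"` or `"TAZ"`.
#' @param taz_threshold see [classify_underdosing()].
#' @return A list with `per_subject` (data frame) and `summary` (medians
#'   and IQRs of the metrics plus the underdosing count).
#' @export
exposure_summary <- function(cohort, drug = c("PIP", "TAZ"),
                             taz_threshold = 2) {
  drug <- match.arg(drug)
  ev <- cohort$events
  ev <- ev[ev$DRUG == drug & ev$EVID == 0, , drop = FALSE]
  per <- lapply(split(ev, ev$ID), function(d) {
    t1 <- max(d$TIME)
    cpl <- d$DV[d$MATRIX == "plasma" & d$TIME == t1][1]
    cpt <- d$DV[d$MATRIX == "peritoneal"][1]
    curi <- d$DV[d$MATRIX == "urine"][1]
    cvac <- d$DV[d$MATRIX == "vac_fluid"][1]
    id <- d$ID[1]
    tru <- cohort$truth[[drug]][[id]]
    dur <- t1 - 0.5
    data.frame(id = id,
               css_plasma = cpl, css_peritoneal = cpt,
               diffusion_pct = if (cpl > 0) diffusion_ratio(cpt, cpl) else NA,
               cl_urine = if (cpl > 0)
                 calculated_clearance(fluid_collection("urine", tru$v_uri,
                                                       curi, dur, cpl))
               else NA,
               cl_vac = if (cpl > 0)
                 calculated_clearance(fluid_collection("vac_fluid", tru$v_vac,
                                                       cvac, dur, cpl))
               else NA,
               underdosed = classify_underdosing(drug, cpt, taz_threshold))
  })
  per <- do.call(rbind, per)
  med_iqr <- function(x) sprintf("%.3g [%.3g-%.3g]",
                                 stats::median(x, na.rm = TRUE),
                                 stats::quantile(x, 0.25, na.rm = TRUE),
                                 stats::quantile(x, 0.75, na.rm = TRUE))
  summary <- data.frame(
    metric = c("Plasma concentration at steady state (mg/L)",
               "Peritoneal fluid concentration (mg/L)",
               "Peritoneal diffusion (%)",
               "Calculated renal clearance (L/h)",
               "Calculated VAC clearance (L/h)",
               "Drug underdosing (n)"),
    value = c(med_iqr(per$css_plasma), med_iqr(per$css_peritoneal),
              med_iqr(per$diffusion_pct), med_iqr(per$cl_urine),
              med_iqr(per$cl_vac), sprintf("%d", sum(per$underdosed))))
  list(per_subject = per, summary = summary)
}
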