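#' Structural two-compartment parameters
#'
#' Kinetic parameters of the two-compartment plasma--peritoneal model with
#' elimination from both compartments: renal (or RRT) elimination `Cl1` from
#' the central compartment and drainage-route elimination `Cl2` (the
#' negative-pressure dressing circuit) from the peritoneal compartment, with
#' intercompartmental clearance `Q`.
#'
#' @param V1 central volume of distribution (L), > 0.
#' @param V2 peritoneal volume of distribution (L), > 0.
#' @param Q intercompartmental clearance (L/h), > 0.
#' @param Cl1 central (renal/RRT) clearance (L/h), > 0.
#' @param Cl2 peritoneal (drainage-route) clearance (L/h), >= 0.
#' @return An object of class `structural_params`.
#' @examples
#' p <- structural_params(V1 = 21.2, V2 = 5, Q = 23.8, Cl1 = 38.7, Cl2 = 5.6)
#' rate_constants(p)
#' @export
structural_params <- function(V1, V2, Q, Cl1, Cl2) {
  assert_num(V1, "V1", positive = TRUE, len = 1)
  assert_num(V2, "V2", positive = TRUE, len = 1)
  assert_num(Q, "Q", positive = TRUE, len = 1)
  assert_num(Cl1, "Cl1", positive = TRUE, len = 1)
  assert_num(Cl2, "Cl2", nonneg = TRUE, len = 1)
  structure(list(V1 = V1, V2 = V2, Q = Q, Cl1 = Cl1, Cl2 = Cl2),
            class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat("Two-compartment structural parameters (mg, L, h):\n")
  cat(sprintf("  V1 = %.4g L   V2 = %.4g L\n", x$V1, x$V2))
  cat(sprintf("  Q  = %.4g L/h Cl1 = %.4g L/h  Cl2 = %.4g L/h\n",
              x$Q, x$Cl1, x$Cl2))
  invisible(x)
}

#' First-order rate constants of the two-compartment model
#'
#' Converts clearance/volume parameters to the micro rate constants
#' `k10 = Cl1/V1`, `k12 = Q/V1`, `k21 = Q/V2`, `k20 = Cl2/V2`.
#'
#' @param p a [structural_params()] object.
#' @return Named numeric vector with elements `k10`, `k12`, `k21`, `k20`
#'   (1/h).
#' @export
rate_constants <- function(p) {
  if (!inherits(p, "structural_params")) stopf("'p' must be structural_params")
  c(k10 = p$Cl1 / p$V1, k12 = p$Q / p$V1,
    k21 = p$Q / p$V2, k20 = p$Cl2 / p$V2)
}

#' Zero-order infusion schedule
#'
#' A set of zero-order inputs into the central compartment. Overlapping
#' events are allowed; their rates add.
#'
#' @param start start times (h), >= 0.
#' @param duration durations (h), > 0; `Inf` marks an open-ended continuous
#'   infusion.
#' @param rate infusion rates (mg/h), >= 0.
#' @return An object of class `dose_schedule` (data frame).
#' @export
dose_schedule <- function(start = numeric(), duration = numeric(),
                          rate = numeric()) {
  n <- length(start)
  if (length(duration) != n || length(rate) != n)
    stopf("start, duration, rate must have equal length")
  if (n) {
    assert_num(start, "start", nonneg = TRUE)
    assert_num(duration, "duration", positive = TRUE, finite = FALSE)
    assert_num(rate, "rate", nonneg = TRUE)
  }
  structure(data.frame(start = as.numeric(start),
                       duration = as.numeric(duration),
                       rate = as.numeric(rate)),
            class = c("dose_schedule", "data.frame"))
}

#' Loading-dose plus continuous-infusion schedule
#'
#' The study administration scheme: a 30-min zero-order loading infusion
#' followed immediately by an uninterrupted continuous infusion.
#'
#' @param loading_mg loading amount (mg) given over `load_duration` hours.
#' @param daily_mg continuous daily amount (mg per 24 h).
#' @param load_duration loading infusion duration (h), default 0.5.
#' @return A [dose_schedule()].
#' @export
regimen_schedule <- function(loading_mg, daily_mg, load_duration = 0.5) {
  assert_num(loading_mg, "loading_mg", positive = TRUE, len = 1)
  assert_num(daily_mg, "daily_mg", positive = TRUE, len = 1)
  dose_schedule(start = c(0, load_duration),
                duration = c(load_duration, Inf),
                rate = c(loading_mg / load_duration, daily_mg / 24))
}

## Vectorised propagation of the linear two-compartment system over one
## segment of constant input rate. State (A1, A2) in mg; returns the state
## dt hours later. Uses the closed-form matrix exponential of the 2x2
## system (Lagrange form e^{Kt} = alpha*I + phi*K), so the solution is exact
## per segment. All arguments may be vectors (recycled to common length).
twocpt_step <- function(A1, A2, k10, k12, k21, k20, rate, dt) {
  a <- k10 + k12
  b <- k12
  cc <- k21
  d <- k21 + k20
  det <- a * d - b * cc          # > 0 whenever k10 > 0
  Ass1 <- rate * d / det
  Ass2 <- rate * b / det
  disc <- sqrt(pmax((a - d)^2 + 4 * b * cc, 0))
  l1 <- (-(a + d) + disc) / 2
  l2 <- (-(a + d) - disc) / 2
  E1 <- exp(l1 * dt)
  E2 <- exp(l2 * dt)
  phi <- ifelse(disc > 1e-12, (E1 - E2) / (l1 - l2), dt * E1)
  alpha <- E1 - phi * l1
  u1 <- A1 - Ass1
  u2 <- A2 - Ass2
  list(A1 = Ass1 + alpha * u1 + phi * (-a * u1 + cc * u2),
       A2 = Ass2 + alpha * u2 + phi * (b * u1 - d * u2))
}

## One-segment propagation plus the exact integral of the amounts over the
## segment: int_0^h A(t) dt = Ass*h + (int alpha) u0 + (int phi) K u0,
## with u0 the initial deviation from the segment steady state. Used for
## cumulative urine/VAC collections, which are integrals of Cl*C over the
## collection interval.
twocpt_step_integral <- function(A1, A2, k10, k12, k21, k20, rate, h) {
  a <- k10 + k12
  b <- k12
  cc <- k21
  d <- k21 + k20
  det <- a * d - b * cc
  Ass1 <- rate * d / det
  Ass2 <- rate * b / det
  disc <- sqrt(pmax((a - d)^2 + 4 * b * cc, 0))
  l1 <- (-(a + d) + disc) / 2
  l2 <- (-(a + d) - disc) / 2
  E1 <- exp(l1 * h)
  E2 <- exp(l2 * h)
  phi <- ifelse(disc > 1e-12, (E1 - E2) / (l1 - l2), h * E1)
  alpha <- E1 - phi * l1
  iE1 <- (E1 - 1) / l1
  iE2 <- (E2 - 1) / l2
  iphi <- ifelse(disc > 1e-12, (iE1 - iE2) / (l1 - l2),
                 (h * E1 - iE1) / l1)
  ialpha <- iE1 - iphi * l1
  u1 <- A1 - Ass1
  u2 <- A2 - Ass2
  Ku1 <- -a * u1 + cc * u2
  Ku2 <- b * u1 - d * u2
  list(A1 = Ass1 + alpha * u1 + phi * Ku1,
       A2 = Ass2 + alpha * u2 + phi * Ku2,
       I1 = Ass1 * h + ialpha * u1 + iphi * Ku1,
       I2 = Ass2 * h + ialpha * u2 + iphi * Ku2)
}

## Piecewise-constant rate from a dose_schedule at segment level: given
## sorted breakpoints, the total rate active on [bp[i], bp[i+1]).
segment_rates <- function(sched, breakpoints) {
  ends <- sched$start + sched$duration
  vapply(seq_len(length(breakpoints)), function(i) {
    t0 <- breakpoints[i]
    sum(sched$rate[sched$start <= t0 + 1e-12 & ends > t0 + 1e-12])
  }, numeric(1))
}

#' Simulate a concentration--time profile
#'
#' Solves the two-compartment system
#' `dA1/dt = R(t) - (k10 + k12) A1 + k21 A2`,
#' `dA2/dt = k12 A1 - (k21 + k20) A2`
#' under piecewise-constant zero-order input, exactly (closed-form matrix
#' exponential per segment), starting from a drug-naive state (A1 = A2 = 0).
#'
#' @param p a [structural_params()] object.
#' @param schedule a [dose_schedule()].
#' @param times sorted non-negative time grid (h).
#' @return An object of class `concentration_profile`: data frame with
#'   columns `time`, `A1`, `A2` (mg) and `C1`, `C2` (mg/L).
#' @export
simulate_profile <- function(p, schedule, times) {
  if (!inherits(p, "structural_params")) stopf("'p' must be structural_params")
  if (!inherits(schedule, "dose_schedule"))
    stopf("'schedule' must be a dose_schedule")
  assert_num(times, "times", nonneg = TRUE)
  if (is.unsorted(times)) stopf("'times' must be sorted increasing")
  k <- rate_constants(p)
  bp <- sort(unique(c(0, schedule$start,
                      schedule$start + schedule$duration, times)))
  bp <- bp[is.finite(bp)]
  rates <- segment_rates(schedule, bp)
  nA1 <- numeric(length(bp))
  nA2 <- numeric(length(bp))
  A1 <- 0; A2 <- 0
  for (i in seq_along(bp)) {
    nA1[i] <- A1; nA2[i] <- A2
    if (i < length(bp)) {
      st <- twocpt_step(A1, A2, k["k10"], k["k12"], k["k21"], k["k20"],
                        rates[i], bp[i + 1] - bp[i])
      A1 <- st$A1; A2 <- st$A2
    }
  }
  idx <- match(times, bp)
  out <- data.frame(time = times, A1 = nA1[idx], A2 = nA2[idx])
  out$C1 <- out$A1 / p$V1
  out$C2 <- out$A2 / p$V2
  class(out) <- c("concentration_profile", "data.frame")
  out
}

#' Steady-state concentrations under constant infusion
#'
#' Closed form for an indefinite constant-rate infusion into the central
#' compartment: `C1ss = rate / (Cl1 + Q*Cl2/(Q + Cl2))` and
#' `C2ss = C1ss * Q/(Q + Cl2)`.
#'
#' @param p a [structural_params()] object.
#' @param rate constant infusion rate (mg/h), >= 0.
#' @return Named numeric vector `c(C1ss, C2ss)` in mg/L.
#' @examples
#' p <- structural_params(21.213, 5, 23.833, 38.739, 5.567)
#' steady_state(p, 16000 / 24)  # 16 g/day continuous
#' @export
steady_state <- function(p, rate) {
  if (!inherits(p, "structural_params")) stopf("'p' must be structural_params")
  assert_num(rate, "rate", nonneg = TRUE)
  C1 <- rate / (p$Cl1 + p$Q * p$Cl2 / (p$Q + p$Cl2))
  c(C1ss = unname(C1), C2ss = unname(C1 * p$Q / (p$Q + p$Cl2)))
}
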