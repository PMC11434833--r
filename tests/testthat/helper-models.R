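## shared fixtures: reference parameter sets and quick cohort builders

pip_pop <- pip_reference_params()
taz_pop <- taz_reference_params()

## a small noiseless parameter set for identity checks
noiseless <- function(pop) {
  pop$omegaV1 <- 0; pop$omegaCl1 <- 0; pop$omegaCl2 <- 0
  pop$gammaCl1 <- 0; pop$bC1 <- 0; pop$bC2 <- 0
  pop
}

## random positive structural parameter sets for property tests
random_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    structural_params(V1 = stats::runif(1, 5, 60),
                      V2 = stats::runif(1, 2, 15),
                      Q = stats::runif(1, 5, 50),
                      Cl1 = stats::runif(1, 1, 50),
                      Cl2 = stats::runif(1, 0, 15)))
}

## independent adaptive-ODE oracle for the two-compartment system
odesolve_profile <- function(p, schedule, times) {
  k <- rate_constants(p)
  ends <- schedule$start + schedule$duration
  rate_at <- function(t) {
    sum(schedule$rate[schedule$start <= t + 1e-12 & ends > t + 1e-12])
  }
  rhs <- function(t, A, parms) {
    list(c(rate_at(t) - (k[["k10"]] + k[["k12"]]) * A[1] + k[["k21"]] * A[2],
           k[["k12"]] * A[1] - (k[["k21"]] + k[["k20"]]) * A[2]))
  }
  bp <- sort(unique(c(times, schedule$start, ends[is.finite(ends)])))
  o <- deSolve::lsoda(c(0, 0), c(0, bp), rhs, NULL,
                      rtol = 1e-10, atol = 1e-10)
  idx <- match(times, o[, 1])
  list(C1 = o[idx, 2] / p$V1, C2 = o[idx, 3] / p$V2)
}
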