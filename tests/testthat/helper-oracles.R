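# Independent oracles and small fixture builders. These deliberately avoid
# the package's analytic concentration path so they can stand as
# cross-checks against it.

# Numerical ODE solution of the two-compartment infusion system (amounts):
#   dA1/dt = R(t) - (k10 + k12) A1 + k21 A2
#   dA2/dt = k12 A1 - k21 A2
# integrated segment-by-segment between infusion breakpoints so the forcing
# is constant within each call to the stiff solver.
ode_conc_oracle <- function(times, doses, CL, V1, Q, V2,
                            rtol = 1e-11, atol = 1e-13) {
  k10 <- CL / V1; k12 <- Q / V1; k21 <- Q / V2
  deriv <- function(t, y, parms) {
    list(c(parms$rate - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  }
  brk <- sort(unique(c(0, doses$start_time,
                       doses$start_time + doses$infusion_duration, times)))
  y <- c(0, 0)
  out <- setNames(rep(NA_real_, length(times)), NULL)
  if (0 %in% times) out[times == 0] <- 0
  for (s in seq_len(length(brk) - 1)) {
    t0 <- brk[s]; t1 <- brk[s + 1]
    active <- doses$start_time <= t0 &
      (doses$start_time + doses$infusion_duration) > t0
    rate <- sum(doses$amount[active] / doses$infusion_duration[active])
    sol <- deSolve::lsoda(y, c(t0, t1), deriv, parms = list(rate = rate),
                          rtol = rtol, atol = atol)
    y <- as.numeric(sol[nrow(sol), 2:3])
    hit <- which(abs(times - t1) < 1e-12)
    if (length(hit)) out[hit] <- y[1] / V1
  }
  out
}

# Closed-form one-compartment infusion concentration (single dose),
# written independently of the package's solver.
one_cmt_conc_oracle <- function(t, dose, dur, CL, V1) {
  k <- CL / V1
  R0 <- dose / dur
  tinf <- pmin(t, dur)
  c0 <- R0 / CL * (1 - exp(-k * tinf))
  ifelse(t <= 0, 0, c0 * exp(-k * pmax(t - dur, 0)))
}

# Adaptive-quadrature marginal -2 log-likelihood for a one-compartment model
# with additive error and a single random effect on CL (exponential IIV).
# Brute-force oracle for the Laplace/FOCE approximation.
quadrature_ofv_oracle <- function(data, CL, V1, omega_cl, sigma_add,
                                  dose, dur) {
  total <- 0
  for (id in unique(data$ID)) {
    sub <- data[data$ID == id & data$EVID == 0, ]
    lik <- function(eta) {
      vapply(eta, function(e) {
        f <- one_cmt_conc_oracle(sub$TIME, dose, dur, CL * exp(e), V1)
        exp(sum(dnorm(sub$DV, f, sigma_add, log = TRUE))) *
          dnorm(e, 0, omega_cl)
      }, 0)
    }
    L <- integrate(lik, -6 * omega_cl, 6 * omega_cl, rel.tol = 1e-10)$value
    total <- total - 2 * log(L)
  }
  total
}

# Small synthetic datasets used across estimation/diagnostics tests.
small_1cmt_spec <- function(omega_cl = 0.25, sigma_prop = 0.05,
                            effects = list()) {
  model_spec(1, c(CL = 6, V1 = 35), effects,
             variance_model(c(CL = omega_cl), sigma_prop = sigma_prop))
}

small_dataset <- function(n = 10, seed = 42, spec = small_1cmt_spec()) {
  generate_dataset(cohort_config(n_subjects = n, seed = seed, spec = spec))
}

# cheap fit controls for tests that exercise behavior, not recovery quality
fast_ctl <- list(n_starts = 1L, presearch_max = 150L, eval_max = 500L,
                 iter_max = 200L, restarts = 1L, hessian = FALSE)
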