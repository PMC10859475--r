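test_that("microconstants match the eigenvalue oracle and satisfy root identities", {
  p <- pk_params(CL = 6.37, V1 = 32.1, Q = 39.7, V2 = 113)
  mc <- microconstants(p)
  expect_equal(mc[["k10"]], 6.37 / 32.1)
  expect_equal(mc[["k12"]], 39.7 / 32.1)
  expect_equal(mc[["k21"]], 39.7 / 113)
  # oracle: alpha/beta are minus the eigenvalues of the 2x2 rate matrix
  A <- matrix(c(-(mc[["k10"]] + mc[["k12"]]), mc[["k21"]],
                mc[["k12"]], -mc[["k21"]]), 2, 2, byrow = TRUE)
  ev <- sort(-Re(eigen(A)$values), decreasing = TRUE)
  expect_equal(unname(mc[c("alpha", "beta")]), ev, tolerance = 1e-12)
  expect_equal(mc[["alpha"]] * mc[["beta"]], mc[["k10"]] * mc[["k21"]])
  expect_equal(mc[["alpha"]] + mc[["beta"]],
               mc[["k10"]] + mc[["k12"]] + mc[["k21"]])
  expect_gt(mc[["beta"]], 0)

  # frozen values from the eigen oracle
  expect_equal(unname(mc[c("alpha", "beta")]), c(1.7466137, 0.0399162),
               tolerance = 1e-6)

  # Q -> 0 decouples the compartments
  mc0 <- microconstants(pk_params(6.37, 32.1, 1e-9, 113))
  expect_equal(mc0[["alpha"]], 6.37 / 32.1, tolerance = 1e-6)
  expect_lt(mc0[["beta"]], 1e-9)

  # symmetric case
  mc1 <- microconstants(pk_params(1, 1, 1, 1))
  expect_equal(mc1[["alpha"]] + mc1[["beta"]], 3)
  expect_equal(mc1[["alpha"]] * mc1[["beta"]], 1)

  expect_error(pk_params(-1, 32.1, 39.7, 113), "positive")
})

test_that("concentration is zero pre-dose, linear in dose, and superposes", {
  p <- pk_params(6.37, 32.1, 39.7, 113)
  d1 <- dose_events(0, 100)
  expect_equal(pk_concentration(0, d1, p), 0)
  expect_error(pk_concentration(-1, d1, p), ">= 0")

  tt <- c(0.25, 0.5, 0.75, 2, 11.9, 30)
  d2 <- dose_events(c(0, 12), c(100, 50))
  c2 <- pk_concentration(tt, d2, p)
  # linearity
  d2x <- dose_events(c(0, 12), c(200, 100))
  expect_equal(pk_concentration(tt, d2x, p), 2 * c2, tolerance = 1e-12)
  # superposition of single-dose solutions
  cs <- pk_concentration(tt, dose_events(0, 100), p) +
    pk_concentration(tt, dose_events(12, 50), p)
  expect_equal(c2, cs, tolerance = 1e-12)
})

test_that("during/post-infusion branches are continuous at end of infusion", {
  set.seed(11)
  for (i in 1:10) {
    p <- pk_params(runif(1, 1, 20), runif(1, 10, 80), runif(1, 5, 60),
                   runif(1, 40, 200))
    dur <- runif(1, 0.25, 2)
    d <- dose_events(0, 100, dur)
    eps <- 1e-9
    lo <- pk_concentration(dur - eps, d, p)
    hi <- pk_concentration(dur + eps, d, p)
    expect_lt(abs(hi - lo) / lo, 1e-6)
    # exact branch boundary
    at <- pk_concentration(dur, d, p)
    expect_lt(abs(at - lo) / lo, 1e-6)
  }
})

test_that("analytic concentrations agree with the ODE oracle", {
  skip_if_not_installed("deSolve")
  set.seed(21)
  for (i in 1:8) {
    CL <- runif(1, 2, 15); V1 <- runif(1, 15, 60)
    Q <- runif(1, 10, 60); V2 <- runif(1, 50, 200)
    d <- dose_events(c(0, 12, 24), c(100, 50, 50), 0.5)
    tt <- sort(runif(4, 0.1, 30))
    ana <- pk_concentration(tt, d, pk_params(CL, V1, Q, V2))
    ode <- ode_conc_oracle(tt, d, CL, V1, Q, V2)
    expect_equal(ana, ode, tolerance = 1e-7)
  }
})

test_that("trapezoidal AUC handles canonical shapes and validates input", {
  expect_equal(auc_trapezoid(c(0, 1), c(0, 0)), 0)
  expect_equal(auc_trapezoid(c(0, 1, 2), c(0, 2, 0)), 2)
  expect_error(auc_trapezoid(c(1, 0), c(1, 1)), "increasing")
  expect_error(auc_trapezoid(c(0, 1), c(-1, 1)), "non-negative")
})

test_that("steady-state AUC matches the dose/CL identity and accumulates monotonically", {
  p <- pk_params(6.37, 32.1, 39.7, 113)
  reg <- regimen(50, loading_dose = 100)
  a_sup <- steady_state_auc24(reg, p)
  expect_equal(as.numeric(a_sup), 100 / 6.37, tolerance = 0.005)
  a_ana <- steady_state_auc24(reg, p, method = "analytic")
  expect_equal(as.numeric(a_ana), 100 / 6.37, tolerance = 1e-12)
  # doubling the dose doubles the AUC
  a2 <- steady_state_auc24(regimen(100, loading_dose = 200), p, "analytic")
  expect_equal(as.numeric(a2), 2 * as.numeric(a_ana))

  # one-compartment degenerate limit (Q ~ 0) matches the closed form
  p1 <- pk_params(6.37, 32.1, 1e-8, 113)
  a1 <- steady_state_auc24(regimen(50), p1, method = "superposition",
                           min_doses = 40)
  expect_equal(as.numeric(a1), 100 / 6.37, tolerance = 0.005)

  # accumulation: trough concentration rises monotonically toward plateau
  doses <- regimen_doses(reg, n_doses = 12)
  troughs <- vapply(2:12, function(k)
    pk_concentration(k * 12 - 1e-9,
                     doses[seq_len(k), , drop = FALSE], p), 0)
  expect_true(all(diff(troughs) > 0))
  # per-interval AUC converges to maintenance dose / CL
  tau_auc <- attr(steady_state_auc24(reg, p, min_doses = 30), "auc_tau")
  expect_equal(tau_auc, 50 / 6.37, tolerance = 0.005)
})
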