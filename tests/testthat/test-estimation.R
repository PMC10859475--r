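test_that("the conditional -2 log-likelihood matches hand computation", {
  # one observation hit exactly, sigma_prop = 1, eta = 0, unit omegas:
  # ln(2*pi) + ln(f^2) + k*ln(2*pi)
  spec <- model_spec(1, c(CL = 6, V1 = 35), variance = variance_model(
    c(CL = 1, V1 = 1), sigma_prop = 1))
  doses <- data.frame(ID = 1, TIME = 0, EVID = 1, AMT = 100, RATE = 200,
                      DV = NA, MDV = 1)
  f <- pk_concentration(2, dose_events(0, 100), pk_params(6, 35))
  obs <- data.frame(ID = 1, TIME = 2, EVID = 0, AMT = NA, RATE = NA,
                    DV = f, MDV = 0)
  sub <- rbind(doses, obs)
  expect_equal(neg2ll_subject(sub, spec),
               log(2 * pi) + log(f^2) + 2 * log(2 * pi), tolerance = 1e-10)

  # two-observation toy subject against an independent arithmetic oracle
  spec2 <- model_spec(1, c(CL = 6, V1 = 35), variance = variance_model(
    c(CL = 0.3), sigma_prop = 0.1))
  obs2 <- data.frame(ID = 1, TIME = c(1, 5), EVID = 0, AMT = NA, RATE = NA,
                     DV = c(2.4, 1.1), MDV = 0)
  sub2 <- rbind(doses, obs2)
  eta <- c(CL = 0.2)
  f2 <- one_cmt_conc_oracle(c(1, 5), 100, 0.5, 6 * exp(0.2), 35)
  v <- 0.1^2 * f2^2
  expected <- sum(log(2 * pi * v) + (c(2.4, 1.1) - f2)^2 / v) +
    0.2^2 / 0.3^2 + log(2 * pi * 0.3^2)
  expect_equal(neg2ll_subject(sub2, spec2, eta), expected, tolerance = 1e-8)

  # joint scaling of y and f leaves the residual quadratic unchanged
  # (proportional error): scale the dose and the observations together
  n2 <- neg2ll_subject(sub2, spec2, eta)
  sub2s <- sub2
  sub2s$AMT[1] <- 300
  sub2s$RATE[1] <- 600
  sub2s$DV[2:3] <- sub2s$DV[2:3] * 3
  n2s <- neg2ll_subject(sub2s, spec2, eta)
  # only the ln(sigma^2 f^2) terms shift, by 2*ln(3) per observation
  expect_equal(n2s - n2, 2 * 2 * log(3), tolerance = 1e-8)
})

test_that("OFV is additive, order-invariant and hits the degenerate-prior limit", {
  spec <- small_1cmt_spec()
  d <- as.data.frame(small_dataset(n = 6, seed = 5))
  o1 <- as.numeric(ofv(d, spec))

  # invariance to subject and within-subject observation ordering
  perm <- d[order(-d$ID, d$TIME, d$EVID), ]
  expect_equal(as.numeric(ofv(perm, spec)), o1, tolerance = 1e-9)

  # duplicating every subject doubles the OFV exactly
  d2 <- d
  d2$ID <- d2$ID + 100
  expect_equal(as.numeric(ofv(rbind(d, d2), spec)), 2 * o1, tolerance = 1e-8)

  # Omega -> 0 pins the etas at zero: OFV equals the fixed-effects -2ll
  spec0 <- model_spec(1, spec$theta, variance = variance_model(
    c(CL = 1e-7), sigma_prop = spec$variance$sigma_prop))
  specno <- model_spec(1, spec$theta, variance = variance_model(
    sigma_prop = spec$variance$sigma_prop))
  expect_equal(as.numeric(ofv(d, spec0)), as.numeric(ofv(d, specno)),
               tolerance = 1e-3)
})

test_that("the Laplace OFV tracks adaptive quadrature on a small dataset", {
  skip_if_not_installed("deSolve")
  spec_gen <- model_spec(1, c(CL = 6, V1 = 35), variance = variance_model(
    c(CL = 0.3), sigma_add = 0.15, residual_form = "additive"))
  d <- as.data.frame(generate_dataset(
    cohort_config(n_subjects = 3, seed = 8, spec = spec_gen,
                  loading_dose = FALSE, p_high_dose = 0)))
  o_laplace <- as.numeric(ofv(d, spec_gen))
  # oracle needs the full superposed dose history; subjects here receive
  # 50 mg q12h without loading, observed around dose 7
  oracle <- 0
  for (id in unique(d$ID)) {
    sub <- d[d$ID == id, ]
    obs <- sub[sub$EVID == 0, ]
    lik <- function(eta) {
      vapply(eta, function(e) {
        f <- rowSums(vapply(seq(0, 72, by = 12), function(s)
          one_cmt_conc_oracle(obs$TIME - s, 50, 0.5, 6 * exp(e), 35),
          numeric(nrow(obs))))
        exp(sum(dnorm(obs$DV, f, 0.15, log = TRUE))) * dnorm(e, 0, 0.3)
      }, 0)
    }
    L <- integrate(lik, -2.5, 2.5, rel.tol = 1e-10)$value
    oracle <- oracle - 2 * log(L)
  }
  expect_lt(abs(o_laplace - oracle), 2)
})

test_that("fitting recovers fixed effects from (near-)noise-free data", {
  # zero IIV, sigma 0.1%: the fixed effects must come back within 1%
  spec_gen <- model_spec(2, c(CL = 6.37, V1 = 32.1, Q = 39.7, V2 = 113),
                         variance = variance_model(sigma_prop = 0.001))
  d <- generate_dataset(cohort_config(n_subjects = 8, seed = 12,
                                      spec = spec_gen))
  ini <- model_spec(2, c(CL = 4, V1 = 45, Q = 25, V2 = 90),
                    variance = variance_model(sigma_prop = 0.01))
  fit <- fit_ppk(d, spec_gen, initials = ini, control = fast_ctl)
  expect_true(fit$converged)
  est <- setNames(fit$estimates$estimate, fit$estimates$name)
  expect_equal(est[["CL"]], 6.37, tolerance = 0.01)
  expect_equal(est[["V1"]], 32.1, tolerance = 0.01)
  expect_equal(est[["Q"]], 39.7, tolerance = 0.01)
  expect_equal(est[["V2"]], 113, tolerance = 0.01)
  # AIC bookkeeping
  expect_equal(fit$aic, fit$ofv + 2 * fit$npar)

  # refitting from the optimum stays at the optimum
  fit2 <- fit_ppk(d, fit$spec, control = fast_ctl)
  expect_lt(abs(fit2$ofv - fit$ofv), 0.05)
})

test_that("two-compartment data prefer the two-compartment model by AIC", {
  spec_gen <- model_spec(2, c(CL = 6.37, V1 = 32.1, Q = 39.7, V2 = 113),
                         variance = variance_model(c(CL = 0.25, V1 = 0.3),
                                                   sigma_prop = 0.05))
  d <- generate_dataset(cohort_config(n_subjects = 12, seed = 30,
                                      spec = spec_gen))
  fit2c <- fit_ppk(d, spec_gen, control = fast_ctl)
  spec1c <- model_spec(1, c(CL = 6, V1 = 60),
                       variance = variance_model(c(CL = 0.25, V1 = 0.3),
                                                 sigma_prop = 0.05))
  fit1c <- fit_ppk(d, spec1c, control = fast_ctl)
  expect_true(fit2c$converged && fit1c$converged)
  expect_lt(fit2c$aic, fit1c$aic)
})
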