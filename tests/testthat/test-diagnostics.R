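test_that("GOF quantities collapse correctly when the model is exact", {
  spec <- small_1cmt_spec(omega_cl = 0.2, sigma_prop = 0.02)
  d <- as.data.frame(small_dataset(n = 6, seed = 71, spec = spec))
  ev <- fit_ppk(d, spec, estimate = FALSE)
  g <- gof_quantities(d, ev)
  # feed the population predictions back as data: residuals vanish
  d2 <- d
  d2$DV[d2$EVID == 0] <- g$PRED
  ev2 <- fit_ppk(d2, spec, estimate = FALSE)
  g2 <- gof_quantities(d2, ev2)
  expect_equal(g2$PRED, g2$DV, tolerance = 1e-10)
  # under proportional error the conditional eta mode sits a hair below 0
  # (the ln-variance term rewards smaller predictions), so IPRED is close
  # to but not exactly the data
  expect_equal(g2$IPRED, g2$DV, tolerance = 1e-2)
  expect_lt(max(abs(g2$CWRES)), 0.05)
})

test_that("time after dose follows the dosing schedule", {
  spec <- small_1cmt_spec()
  d <- as.data.frame(small_dataset(n = 2, seed = 72, spec = spec))
  ev <- fit_ppk(d, spec, estimate = FALSE)
  g <- gof_quantities(d, ev)
  # design: doses q12h from 0, samples at 72 (pre-dose) .. 84
  expect_equal(g$TAD[g$TIME == 73][1], 1)
  expect_equal(g$TAD[g$TIME == 72][1], 12)  # pre-dose sample -> previous dose
  expect_equal(g$TAD[g$TIME == 84][1], 12)
})

test_that("CWRES are calibrated on data simulated under the true model", {
  # full design: ~751 observations after completely-at-random dropout
  cfg <- cohort_config(n_subjects = 98, seed = 73, dropout = 33 / 784)
  d <- as.data.frame(generate_dataset(cfg))
  ev <- fit_ppk(d, tigecycline_final_model(), estimate = FALSE)
  g <- gof_quantities(d, ev)
  expect_gt(nrow(g), 700)
  expect_lt(abs(mean(g$CWRES)), 0.1)
  expect_gt(sd(g$CWRES), 0.8)
  expect_lt(sd(g$CWRES), 1.2)
})

test_that("bootstrap reproduces the identity resample and orders percentiles", {
  spec <- small_1cmt_spec()
  d <- as.data.frame(small_dataset(n = 8, seed = 74, spec = spec))
  fit <- fit_ppk(d, spec, control = fast_ctl)
  bs1 <- ppk_bootstrap(d, spec, n_resamples = 1, control = fast_ctl,
                       .resampler = function(ids) ids)
  expect_equal(unname(bs1$estimates[1, ]),
               fit$estimates$estimate, tolerance = 1e-4)
  expect_equal(bs1$n_success, 1L)

  bs <- ppk_bootstrap(d, spec, n_resamples = 6, seed = 5, control = fast_ctl)
  expect_true(all(bs$summary$q2.5 <= bs$summary$median + 1e-12))
  expect_true(all(bs$summary$median <= bs$summary$q97.5 + 1e-12))
  expect_false(bs$unreliable)
  # bit-reproducible under the seed
  bs_again <- ppk_bootstrap(d, spec, n_resamples = 6, seed = 5,
                            control = fast_ctl)
  expect_identical(bs$estimates, bs_again$estimates)
  # medians of a correctly specified refit stay near the generating values
  expect_equal(bs$summary$median[bs$summary$name == "CL"], 6,
               tolerance = 0.15)
})

test_that("VPC envelopes cover self-simulated data and collapse without variance", {
  spec <- small_1cmt_spec(omega_cl = 0.3, sigma_prop = 0.05)
  d <- as.data.frame(small_dataset(n = 30, seed = 75, spec = spec))
  v <- ppk_vpc(d, spec, n_replicates = 120, seed = 9)
  b <- v$bins
  inside <- (b$obs_p5 >= b$sim_p5_lo & b$obs_p5 <= b$sim_p5_hi) +
    (b$obs_p50 >= b$sim_p50_lo & b$obs_p50 <= b$sim_p50_hi) +
    (b$obs_p95 >= b$sim_p95_lo & b$obs_p95 <= b$sim_p95_hi)
  expect_gte(mean(inside / 3), 0.9)
  # equivariant under subject relabeling
  d2 <- d
  d2$ID <- 1000 - d2$ID
  v2 <- ppk_vpc(d2, spec, n_replicates = 120, seed = 9)
  expect_equal(v2$bins, v$bins, tolerance = 1e-12)

  # (near-)zero-variance model: envelopes collapse onto the prediction
  spec0 <- model_spec(1, spec$theta, variance = variance_model(
    c(CL = 1e-6), sigma_prop = 1e-6))
  v0 <- ppk_vpc(d, spec0, n_replicates = 40, seed = 9)
  # the across-replicate envelope of every percentile collapses
  for (pc in c("p5", "p50", "p95"))
    expect_lt(max((v0$bins[[paste0("sim_", pc, "_hi")]] -
                     v0$bins[[paste0("sim_", pc, "_lo")]]) /
                    v0$bins[[paste0("sim_", pc, "_hi")]]), 1e-4)
})

test_that("more VPC replicates shrink the Monte Carlo jitter of the envelope", {
  spec <- small_1cmt_spec(omega_cl = 0.3, sigma_prop = 0.05)
  d <- as.data.frame(small_dataset(n = 20, seed = 76, spec = spec))
  edge <- function(R, seed) ppk_vpc(d, spec, n_replicates = R,
                                    seed = seed)$bins$sim_p50_hi[3]
  lo <- vapply(1:6, function(s) edge(25, s), 0)
  hi <- vapply(1:6, function(s) edge(200, s), 0)
  expect_lt(sd(hi), sd(lo))
})
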