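test_that("virtual cohorts honor the stratum covariates and the seed", {
  co0 <- simulate_cohort(50, c(CCR = 80),
                         spec = model_spec(2, tigecycline_final_model()$theta,
                                           tigecycline_final_model()$effects,
                                           variance_model(sigma_prop = 0.02)),
                         seed = 1)
  # no IIV: every virtual patient is the typical patient
  expect_equal(length(unique(co0$CL)), 1L)
  expect_equal(co0$CL[1], 3.09 + (80 / 77) * 3.28, tolerance = 1e-12)

  co1 <- simulate_cohort(200, c(CCR = 80), seed = 7)
  co2 <- simulate_cohort(200, c(CCR = 80), seed = 7)
  expect_identical(co1, co2)

  # lognormal IIV: the sample median CL converges to the typical value
  big <- simulate_cohort(1e5, c(CCR = 80), seed = 8)
  expect_equal(median(big$CL), 3.09 + (80 / 77) * 3.28, tolerance = 0.01)
})

test_that("PTA thresholds are exact for a zero-variance cohort", {
  cohort <- data.frame(CL = 6.37, V1 = 32.1, Q = 39.7, V2 = 113)
  reg <- regimen(50, loading_dose = 100)
  tgt <- pkpd_target("cIAI")         # ratio 6.96
  # AUC24 = 100/6.37 = 15.70; AUC/MIC at MIC 2 = 7.85 >= 6.96
  expect_equal(pta(cohort, reg, mic = 2, tgt), 1)
  # at MIC 4: 3.92 < 6.96
  expect_equal(pta(cohort, reg, mic = 4, tgt), 0)
  # the trapezoid pipeline agrees with the analytic identity
  expect_equal(pta(cohort, reg, 2, tgt, auc_method = "superposition"), 1)
  expect_error(pta(cohort[0, ], reg, 2, tgt), "empty")
  expect_error(pkpd_target("unknown"), "ratio")
})

test_that("a single grid cell reproduces pta() with the derived seed", {
  g <- pta_grid(regimens = list(std = regimen(50, loading_dose = 100)),
                mics = 1, strata = data.frame(family = "CCr", value = "80"),
                targets = list(pkpd_target("cIAI")), n = 500, seed = 3)
  expect_equal(nrow(g), 1L)
  co <- simulate_cohort(500, c(CCR = 80), seed = g$seed[1])
  expect_equal(g$pta[1], pta(co, regimen(50, loading_dose = 100), 1,
                             pkpd_target("cIAI")))
  expect_true(all(g$pta >= 0 & g$pta <= 1))
})

test_that("PTA is monotone in MIC, dose and renal function", {
  strata <- data.frame(family = "CCr", value = c("30", "80", "130"))
  g <- pta_grid(mics = c(0.25, 1, 4), strata = strata,
                targets = list(pkpd_target("cIAI")), n = 2000, seed = 11,
                common_random_numbers = TRUE)
  for (v in c("30", "80", "130")) for (rg in unique(g$regimen)) {
    p <- g$pta[g$value == v & g$regimen == rg][order(
      g$mic[g$value == v & g$regimen == rg])]
    expect_true(all(diff(p) <= 0))
  }
  # high dose dominates under common random numbers
  wide <- merge(g[g$regimen == "std_50mg_q12h", ],
                g[g$regimen == "high_100mg_q12h", ],
                by = c("mic", "family", "value", "target"))
  expect_true(all(wide$pta.y >= wide$pta.x))
  # faster clearance (higher CCr) lowers PTA
  for (m in c(0.25, 1, 4)) for (rg in unique(g$regimen)) {
    p <- g$pta[g$mic == m & g$regimen == rg][order(
      as.numeric(g$value[g$mic == m & g$regimen == rg]))]
    expect_true(all(diff(p) <= 0))
  }
})

test_that("regimen recommendation picks the lowest sufficient dose", {
  reg_attr <- list(std_50mg_q12h = regimen(50, loading_dose = 100),
                   high_100mg_q12h = regimen(100, loading_dose = 200))
  mk_grid <- function(p_std, p_high) {
    g <- data.frame(
      regimen = rep(names(reg_attr), each = 2), mic = rep(c(1, 2), 2),
      family = "reference", value = "median", target = "cIAI",
      pta = c(p_std, p_std, p_high, p_high), n = 100, seed = 1,
      stringsAsFactors = FALSE)
    attr(g, "regimens") <- reg_attr
    class(g) <- c("pta_grid", class(g))
    g
  }
  all_good <- recommend_regimen(mk_grid(1, 1))
  expect_true(all(all_good$recommended == "std_50mg_q12h"))
  none <- recommend_regimen(mk_grid(0, 0))
  expect_true(all(none$recommended == "none attainable"))
  split_case <- recommend_regimen(mk_grid(0.5, 0.95))
  expect_true(all(split_case$recommended == "high_100mg_q12h"))
})

test_that("liver-function strata leave the PTA unchanged", {
  strata <- data.frame(family = "liver", value = c("normal", "abnormal"))
  g <- pta_grid(regimens = list(std = regimen(50, loading_dose = 100)),
                mics = c(0.5, 1), strata = strata,
                targets = list(pkpd_target("cIAI")), n = 3000, seed = 13)
  for (m in c(0.5, 1)) {
    p <- g$pta[g$mic == m]
    expect_lt(abs(diff(p)), 0.03)  # within Monte Carlo error
  }
})
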