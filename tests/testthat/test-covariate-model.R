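test_that("Cockcroft-Gault matches the direct formula and its scaling laws", {
  expect_equal(cockcroft_gault(40, 70, 88.4, "male"), 100 * 70 / 72,
               tolerance = 1e-12)  # 97.22 mL/min
  expect_equal(cockcroft_gault(40, 70, 88.4, "female"),
               0.85 * 100 * 70 / 72, tolerance = 1e-12)  # 82.64
  # doubling SCr halves CCr
  expect_equal(cockcroft_gault(63, 62, 128, 0),
               2 * cockcroft_gault(63, 62, 256, 0))
  # numeric sex coding agrees with labels
  expect_equal(cockcroft_gault(50, 60, 90, 1),
               cockcroft_gault(50, 60, 90, "female"))
  expect_warning(out <- cockcroft_gault(141, 70, 88.4, "male"), "140")
  expect_equal(out, 1)
  expect_error(cockcroft_gault(-5, 70, 88.4, "male"), "> 0")
})

test_that("covariate functional forms obey their normalization identities", {
  # at the median: linear adds theta_cov, exponential multiplies e^theta,
  # power is the identity
  expect_equal(apply_covariate("linear", 3.09, 3.28, 77, 77), 6.37)
  expect_equal(apply_covariate("exponential", 2, 0.5, 10, 10), 2 * exp(0.5))
  expect_equal(apply_covariate("power", 32.1, 1.95, 61, 61), 32.1)
  expect_equal(apply_covariate("power_categorical", 5, 0.8, 1), 4)
  expect_equal(apply_covariate("categorical", 5, 0.8, 0), 5)
  expect_error(apply_covariate("categorical", 5, 0.8, 2), "0 or 1")
  expect_error(apply_covariate("spline", 1, 1, 1, 1))
  expect_error(apply_covariate("linear", 1, 1, 1, -2), "> 0")
})

test_that("continuous forms are continuous and monotone in the covariate", {
  set.seed(7)
  for (i in 1:20) {
    th_pop <- runif(1, 1, 50)
    th_cov <- runif(1, -2, 2)
    med <- runif(1, 10, 100)
    x <- sort(runif(50, 1, 300))
    for (form in c("linear", "exponential", "power")) {
      y <- apply_covariate(form, th_pop, th_cov, x, med)
      expect_true(all(is.finite(y)))
      d <- diff(y)
      if (th_cov > 0) expect_true(all(d >= -1e-12)) else
        expect_true(all(d <= 1e-12))
    }
  }
})

test_that("the published final model reproduces its printed typical values", {
  # unity normalizations: CCr 77, BW 61, log10 GGT/TBIL/ALB at 1.7/1.2/1.4
  p <- final_model_typicals(c(CCR = 77, WT = 61, GGT = 10^1.7,
                              TBIL = 10^1.2, ALB = 10^1.4))
  expect_equal(unname(unclass(p)[c("CL", "V1", "Q", "V2")]),
               c(6.37, 32.1, 39.7, 113), tolerance = 1e-12)

  # body weight doubling: V1 = 32.1 * 2^1.95
  p2 <- final_model_typicals(c(CCR = 77, WT = 122, GGT = 10^1.7,
                               TBIL = 10^1.2, ALB = 10^1.4))
  expect_equal(p2[["V1"]], 32.1 * 2^1.95, tolerance = 1e-12)
  expect_equal(p2[["V1"]], 124.0, tolerance = 1e-3)

  # Q depends only on the GGT/TBIL log-ratios, not the other covariates
  pa <- final_model_typicals(c(CCR = 130, WT = 90, GGT = 10^(1.7 * 1.1),
                               TBIL = 10^(1.2 * 0.9), ALB = 10^1.3))
  pb <- final_model_typicals(c(CCR = 30, WT = 45, GGT = 10^(1.7 * 1.1),
                               TBIL = 10^(1.2 * 0.9), ALB = 10^1.5))
  expect_equal(pa[["Q"]], pb[["Q"]])
  expect_equal(pa[["Q"]], 39.7 * 1.1^0.956 * 0.9^-0.912, tolerance = 1e-12)

  # a covariate with log10 <= 0 is rejected by name
  expect_error(final_model_typicals(c(CCR = 77, WT = 61, GGT = 0.9,
                                      TBIL = 10^1.2, ALB = 10^1.4)), "GGT")
})

test_that("exponential IIV individualization preserves structure", {
  p <- pk_params(6.37, 32.1, 39.7, 113)
  expect_equal(individualize(p, c(CL = 0, V1 = 0)), p)
  pi <- individualize(p, c(CL = log(2)))
  expect_equal(pi[["CL"]], 2 * 6.37)
  expect_equal(pi[["V1"]], 32.1)
  # positivity for extreme finite eta
  expect_gt(individualize(p, c(V1 = -20))[["V1"]], 0)
  expect_error(individualize(p, c(CL = Inf)), "finite")
  expect_error(individualize(p, c(XX = 1)), "named")

  # lognormal property: geometric mean of draws converges to the typical
  set.seed(99)
  draws <- 6.37 * exp(rnorm(1e5, 0, 0.27))
  expect_equal(exp(mean(log(draws))), 6.37, tolerance = 0.01)
})

test_that("model specs validate structure and round-trip through YAML", {
  spec <- tigecycline_final_model()
  expect_error(model_spec(2, c(CL = 1, V1 = 1)), "theta must contain")
  expect_error(
    model_spec(2, c(CL = 5, V1 = 40, Q = 30, V2 = 100),
               list(covariate_effect("CL", "CCR", "linear", 1, 77),
                    covariate_effect("CL", "CCR", "power", 1, 77))),
    "duplicated")
  expect_error(
    model_spec(1, c(CL = 5, V1 = 40),
               list(covariate_effect("Q", "GGT", "power", 1, 1.7))),
    "not in the structural model")

  path <- tempfile(fileext = ".yaml")
  write_model_spec(spec, path)
  spec2 <- read_model_spec(path)
  expect_equal(spec2, spec)
})
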