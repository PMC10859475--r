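#' Cockcroft-Gault creatinine clearance
#'
#' `CCr = (140 - age) * BW / (72 * SCr[mg/dL])`, multiplied by 0.85 for
#' females. Serum creatinine is taken in umol/L (as reported by the clinical
#' laboratory) and converted internally to mg/dL by dividing by 88.4.
#'
#' @param age years (> 0). Ages >= 140 would give a non-positive numerator;
#'   these produce a warning and the result is floored at `floor_ccr`.
#' @param BW body weight, kg (> 0).
#' @param SCr serum creatinine, umol/L (> 0).
#' @param sex `"male"`/`"female"`, or numeric 0 = male, 1 = female.
#' @param floor_ccr minimum CCr returned (mL/min), default 1.
#' @return Creatinine clearance in mL/min (vectorized).
#' @examples
#' cockcroft_gault(40, 70, 88.4, "male")    # 97.22
#' cockcroft_gault(40, 70, 88.4, "female")  # x 0.85
#' @export
cockcroft_gault <- function(age, BW, SCr, sex, floor_ccr = 1) {
  if (any(age <= 0) || any(BW <= 0) || any(SCr <= 0))
    stop("age, BW and SCr must be > 0")
  female <- if (is.character(sex) || is.factor(sex)) {
    as.character(sex) == "female"
  } else sex == 1
  scr_mgdl <- SCr / 88.4
  ccr <- ((140 - age) * BW) / (72 * scr_mgdl)
  ccr <- ifelse(female, 0.85 * ccr, ccr)
  if (any(age >= 140)) {
    warning("age >= 140 gives a non-positive Cockcroft-Gault numerator; ",
            "flooring CCr at ", floor_ccr, " mL/min")
  }
  pmax(ccr, floor_ccr)
}

.forms <- c("linear", "exponential", "power", "categorical")

.normalize_form <- function(form) {
  if (form == "power_categorical") form <- "categorical"
  match.arg(form, .forms)
}

#' Apply a covariate functional form to a typical parameter value
#'
#' The four covariate-parameter relationship families, with `x` the covariate
#' value normalized by the population median (`x = cov/median`) for the
#' continuous forms, and the raw 0/1 value for the categorical form:
#' * linear: `theta_pop + theta_cov * x`
#' * exponential: `theta_pop * exp(theta_cov * x)`
#' * power: `theta_pop * x^theta_cov`
#' * categorical: `theta_pop * theta_cov^cov` (cov in \{0, 1\})
#'
#' @param form one of `"linear"`, `"exponential"`, `"power"`,
#'   `"categorical"` (alias `"power_categorical"`).
#' @param theta_pop population typical value.
#' @param theta_cov covariate effect.
#' @param cov_value covariate value (0/1 for the categorical form).
#' @param cov_median population median used for normalization (continuous
#'   forms; must be > 0).
#' @return The individual typical parameter value.
#' @examples
#' apply_covariate("linear", 3.09, 3.28, 77, 77)   # 6.37
#' apply_covariate("power", 32.1, 1.95, 61, 61)    # 32.1
#' @export
apply_covariate <- function(form, theta_pop, theta_cov, cov_value,
                            cov_median = NULL) {
  form <- .normalize_form(form)
  if (form == "categorical") {
    if (any(!cov_value %in% c(0, 1)))
      stop("categorical covariate values must be 0 or 1")
    return(theta_pop * theta_cov^cov_value)
  }
  if (is.null(cov_median) || any(cov_median <= 0))
    stop("cov_median must be > 0 for continuous covariate forms")
  x <- cov_value / cov_median
  switch(form,
         linear = theta_pop + theta_cov * x,
         exponential = theta_pop * exp(theta_cov * x),
         power = theta_pop * x^theta_cov)
}

#' Covariate effect definition
#'
#' One covariate-parameter relationship of a model specification.
#'
#' @param parameter one of `"CL"`, `"V1"`, `"Q"`, `"V2"`.
#' @param covariate dataset column name (e.g. `"CCR"`, `"WT"`, `"GGT"`).
#' @param form functional family, see [apply_covariate()].
#' @param theta effect size (also used as the starting value in estimation).
#' @param median normalization constant, on the transformed scale when
#'   `transform = "log10"`. Stored with the model (not recomputed from data)
#'   so published-model simulation is reproducible.
#' @param transform `"identity"` or `"log10"` (covariate is log10-transformed
#'   before normalization; values with log10 <= 0 are rejected).
#' @return An object of class `covariate_effect`.
#' @export
covariate_effect <- function(parameter, covariate, form, theta, median = NULL,
                             transform = c("identity", "log10")) {
  parameter <- match.arg(parameter, c("CL", "V1", "Q", "V2"))
  form <- .normalize_form(form)
  transform <- match.arg(transform)
  if (form != "categorical" && (is.null(median) || median <= 0))
    stop("continuous covariate effects need a positive normalization median")
  structure(list(parameter = parameter, covariate = covariate, form = form,
                 theta = theta, median = median, transform = transform),
            class = "covariate_effect")
}

#' @export
print.covariate_effect <- function(x, ...) {
  cov <- if (x$transform == "log10") paste0("log10(", x$covariate, ")") else x$covariate
  cat(sprintf("<covariate_effect> %s on %s, %s form, theta = %g, median = %s\n",
              cov, x$parameter, x$form, x$theta,
              if (is.null(x$median)) "-" else format(x$median)))
  invisible(x)
}

.effect_x <- function(eff, values) {
  # normalized covariate input for one effect
  v <- values
  if (eff$transform == "log10") {
    if (any(v <= 1))
      stop("covariate ", eff$covariate, " has log10 <= 0; cannot evaluate ",
           "log10-power effect")
    v <- log10(v)
  }
  if (eff$form == "categorical") {
    if (any(!v %in% c(0, 1)))
      stop("categorical covariate ", eff$covariate, " must be 0/1")
    return(v)
  }
  if (eff$form == "power" && any(v <= 0))
    stop("covariate ", eff$covariate, " must be > 0 for a power effect")
  v / eff$median
}

#' Variance model: interindividual and residual variability
#'
#' Interindividual variability (IIV) is exponential,
#' `parameter_i = typical * exp(eta)`, with independent
#' `eta ~ N(0, omega^2)` per parameter; parameters absent from `omega` carry
#' no IIV (omega = 0). Residual variability is additive, proportional
#' (`y = f * (1 + eps)`) or combined. `omega` and `sigma` are standard
#' deviations; the conventional percent reporting is `100 * sd`
#' (approximate %CV), see [sd_to_pct()].
#'
#' @param omega named numeric vector of IIV standard deviations (natural
#'   scale, e.g. 0.27 for 27%), names among CL, V1, Q, V2.
#' @param sigma_prop proportional residual sd (e.g. 0.0202 for 2.02%).
#' @param sigma_add additive residual sd (mg/L).
#' @param residual_form `"proportional"`, `"additive"` or `"combined"`.
#' @return An object of class `variance_model`.
#' @export
variance_model <- function(omega = numeric(),
                           sigma_prop = 0, sigma_add = 0,
                           residual_form = c("proportional", "additive",
                                             "combined")) {
  residual_form <- match.arg(residual_form)
  if (length(omega) && (is.null(names(omega)) ||
                        !all(names(omega) %in% c("CL", "V1", "Q", "V2"))))
    stop("omega must be named with parameters among CL, V1, Q, V2")
  if (any(omega < 0) || sigma_prop < 0 || sigma_add < 0)
    stop("variance components must be >= 0")
  if (residual_form == "proportional" && sigma_prop <= 0)
    stop("proportional residual model needs sigma_prop > 0")
  if (residual_form == "additive" && sigma_add <= 0)
    stop("additive residual model needs sigma_add > 0")
  if (residual_form == "combined" && (sigma_prop <= 0 || sigma_add <= 0))
    stop("combined residual model needs both sigma components > 0")
  structure(list(omega = omega, sigma_prop = sigma_prop,
                 sigma_add = sigma_add, residual_form = residual_form),
            class = "variance_model")
}

#' Convert variability standard deviations to/from percent reporting
#'
#' Population-PK convention: omega and sigma are reported as
#' `100 * sqrt(variance)` percent (approximate %CV for exponential /
#' proportional models).
#'
#' @param sd standard deviation on the natural scale (e.g. 0.27).
#' @param pct percent value (e.g. 27.0).
#' @return The converted value.
#' @export
sd_to_pct <- function(sd) 100 * sd

#' @rdname sd_to_pct
#' @export
pct_to_sd <- function(pct) pct / 100

#' Individualize typical parameters with exponential random effects
#'
#' `parameter_i = typical * exp(eta)`; parameters without IIV take `eta = 0`.
#' Positivity is preserved for any finite `eta`.
#'
#' @param typicals a [pk_params()].
#' @param eta named numeric vector of random effects (subset of the parameter
#'   names; missing entries are 0).
#' @return A [pk_params()] with individualized values.
#' @examples
#' individualize(pk_params(6.37, 32.1, 39.7, 113), c(CL = log(2)))
#' @export
individualize <- function(typicals, eta = numeric()) {
  if (!inherits(typicals, "pk_params"))
    typicals <- do.call(pk_params, as.list(typicals))
  if (length(eta)) {
    if (is.null(names(eta)) || !all(names(eta) %in% names(typicals)))
      stop("eta must be named with parameters of the model")
    if (any(!is.finite(eta))) stop("eta must be finite")
  }
  out <- unclass(typicals)
  for (nm in names(eta)) out[[nm]] <- out[[nm]] * exp(eta[[nm]])
  args <- as.list(out)
  do.call(pk_params, args)
}
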