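#' Model specification
#'
#' Structural model (number of compartments), covariate effects, variance
#' model and starting values, driving estimation, selection, simulation and
#' diagnostics.
#'
#' Covariate effects compose NONMEM-style: for each parameter,
#' `theta_i = (theta_pop + sum of linear terms) * product of multiplicative
#' factors` (exponential/power/categorical forms multiply).
#'
#' @param n_compartments 1 or 2.
#' @param theta named numeric vector of structural typical values:
#'   `CL`, `V1` and, for two compartments, `Q`, `V2`. These are the model's
#'   stated values (for simulation) and the defaults from which estimation
#'   starts unless `initials` is given to [fit_ppk()].
#' @param effects list of [covariate_effect()]s; no duplicated
#'   (parameter, covariate) pair, and only parameters present in the
#'   structural model.
#' @param variance a [variance_model()].
#' @return An object of class `model_spec`.
#' @examples
#' model_spec(2, c(CL = 5, V1 = 40, Q = 30, V2 = 100),
#'            variance = variance_model(c(CL = 0.3), sigma_prop = 0.1))
#' @export
model_spec <- function(n_compartments = 2, theta, effects = list(),
                       variance = variance_model(sigma_prop = 0.1)) {
  n_compartments <- as.integer(n_compartments)
  if (!n_compartments %in% 1:2) stop("n_compartments must be 1 or 2")
  need <- if (n_compartments == 2) c("CL", "V1", "Q", "V2") else c("CL", "V1")
  if (!all(need %in% names(theta)))
    stop("theta must contain ", paste(need, collapse = ", "))
  theta <- theta[need]
  if (any(theta <= 0)) stop("structural typical values must be > 0")
  if (!all(vapply(effects, inherits, TRUE, "covariate_effect")))
    stop("effects must be a list of covariate_effect objects")
  for (e in effects)
    if (!e$parameter %in% need)
      stop("covariate effect on ", e$parameter,
           " but that parameter is not in the structural model")
  keys <- vapply(effects, function(e) paste(e$parameter, e$covariate), "")
  if (anyDuplicated(keys))
    stop("duplicated (parameter, covariate) pair in effects")
  if (!inherits(variance, "variance_model")) stop("variance must be a variance_model")
  if (length(variance$omega) && !all(names(variance$omega) %in% need))
    stop("omega names must be structural parameters of the model")
  structure(list(n_compartments = n_compartments, theta = theta,
                 effects = effects, variance = variance),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %d-compartment, %d covariate effect(s)\n",
              x$n_compartments, length(x$effects)))
  cat("  theta:", paste(sprintf("%s=%g", names(x$theta), x$theta),
                        collapse = ", "), "\n")
  for (e in x$effects) {
    cov <- if (e$transform == "log10") paste0("log10(", e$covariate, ")") else e$covariate
    cat(sprintf("  %s ~ %s [%s], theta=%g, median=%s\n", e$parameter, cov,
                e$form, e$theta,
                if (is.null(e$median)) "-" else format(e$median)))
  }
  om <- x$variance$omega
  cat("  omega (%):", if (length(om))
    paste(sprintf("%s=%g", names(om), sd_to_pct(om)), collapse = ", ")
    else "none", "\n")
  cat(sprintf("  residual: %s (sigma_prop=%g%%, sigma_add=%g)\n",
              x$variance$residual_form, sd_to_pct(x$variance$sigma_prop),
              x$variance$sigma_add))
  invisible(x)
}

#' Add or drop a covariate effect
#'
#' @param spec a [model_spec()].
#' @param effect a [covariate_effect()] to add.
#' @return The modified [model_spec()].
#' @export
spec_add_effect <- function(spec, effect) {
  model_spec(spec$n_compartments, spec$theta, c(spec$effects, list(effect)),
             spec$variance)
}

#' @rdname spec_add_effect
#' @param parameter,covariate identify the effect to drop.
#' @export
spec_drop_effect <- function(spec, parameter, covariate) {
  keep <- !vapply(spec$effects, function(e)
    e$parameter == parameter && e$covariate == covariate, TRUE)
  if (all(keep)) stop("no effect of ", covariate, " on ", parameter)
  model_spec(spec$n_compartments, spec$theta, spec$effects[keep], spec$variance)
}

#' The published final tigecycline model
#'
#' Two-compartment model with proportional residual error and exponential IIV
#' on CL, V1 and Q (none estimable on V2), with the covariate equations
#' (log = log10; normalization constants are fixed with the model):
#' \preformatted{
#' CL (L/h) = 3.09 + (CCr/77) * 3.28
#' V1 (L)   = 32.1 * (BW/61)^1.95
#' Q (L/h)  = 39.7 * (logGGT/1.7)^0.956 * (logTBIL/1.2)^-0.912
#' V2 (L)   = 113 * (BW/61)^1.61 * (logALB/1.4)^4.52
#' }
#' IIV: omega_CL 27.0%, omega_V1 72.5%, omega_Q 18.8%; proportional residual
#' sigma 2.02%.
#'
#' @return A [model_spec()] carrying the published estimates.
#' @export
tigecycline_final_model <- function() {
  model_spec(
    n_compartments = 2,
    theta = c(CL = 3.09, V1 = 32.1, Q = 39.7, V2 = 113),
    effects = list(
      covariate_effect("CL", "CCR", "linear", theta = 3.28, median = 77),
      covariate_effect("V1", "WT", "power", theta = 1.95, median = 61),
      covariate_effect("Q", "GGT", "power", theta = 0.956, median = 1.7,
                       transform = "log10"),
      covariate_effect("Q", "TBIL", "power", theta = -0.912, median = 1.2,
                       transform = "log10"),
      covariate_effect("V2", "WT", "power", theta = 1.61, median = 61),
      covariate_effect("V2", "ALB", "power", theta = 4.52, median = 1.4,
                       transform = "log10")),
    variance = variance_model(
      omega = c(CL = 0.270, V1 = 0.725, Q = 0.188),
      sigma_prop = 0.0202, residual_form = "proportional"))
}

#' Typical (covariate-predicted) parameters under a model specification
#'
#' Evaluates the covariate model at one or more covariate records
#' (`eta = 0`).
#'
#' @param spec a [model_spec()].
#' @param covariates a `data.frame` (or named list/vector for one subject)
#'   with the covariate columns the spec's effects reference (raw scale;
#'   log10 transforms are applied internally).
#' @return A `data.frame` with one row per record and columns CL, V1 (and
#'   Q, V2 for two-compartment models).
#' @export
model_typicals <- function(spec, covariates) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.data.frame(covariates)) covariates <- as.data.frame(as.list(covariates))
  n <- nrow(covariates)
  pars <- names(spec$theta)
  base <- matrix(rep(spec$theta, each = n), nrow = n,
                 dimnames = list(NULL, pars))
  add <- matrix(0, n, length(pars), dimnames = list(NULL, pars))
  mult <- matrix(1, n, length(pars), dimnames = list(NULL, pars))
  for (e in spec$effects) {
    if (!e$covariate %in% names(covariates))
      stop("covariate ", e$covariate, " missing from the covariate record")
    x <- .effect_x(e, covariates[[e$covariate]])
    if (e$form == "linear") add[, e$parameter] <- add[, e$parameter] + e$theta * x
    else if (e$form == "exponential")
      mult[, e$parameter] <- mult[, e$parameter] * exp(e$theta * x)
    else if (e$form == "power")
      mult[, e$parameter] <- mult[, e$parameter] * x^e$theta
    else mult[, e$parameter] <- mult[, e$parameter] * e$theta^x
  }
  out <- as.data.frame((base + add) * mult)
  if (any(as.matrix(out) <= 0))
    stop("covariate model yields a non-positive typical parameter")
  out
}

#' Typical parameters under the published final model
#'
#' Convenience wrapper evaluating [tigecycline_final_model()] at a covariate
#' record with fields `CCR` (mL/min), `WT` (kg), `GGT` (U/L), `TBIL`
#' (umol/L), `ALB` (g/L).
#'
#' @param covariates named list/vector or one-row `data.frame`.
#' @return A [pk_params()] for a single record, otherwise a `data.frame`.
#' @examples
#' final_model_typicals(c(CCR = 77, WT = 61, GGT = 10^1.7,
#'                        TBIL = 10^1.2, ALB = 10^1.4))
#' @export
final_model_typicals <- function(covariates) {
  out <- model_typicals(tigecycline_final_model(), covariates)
  if (nrow(out) == 1)
    return(pk_params(out$CL, out$V1, out$Q, out$V2))
  out
}

#' Read / write a model specification as a declarative YAML file
#'
#' The file holds the structural size, typical values, covariate effects and
#' variance model as nested key-value sections; read-write round-trips are
#' lossless.
#'
#' @param spec a [model_spec()].
#' @param path file path.
#' @return `write_model_spec()` returns `path` invisibly; `read_model_spec()`
#'   returns a [model_spec()].
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  x <- list(
    n_compartments = spec$n_compartments,
    theta = as.list(spec$theta),
    effects = lapply(spec$effects, function(e)
      list(parameter = e$parameter, covariate = e$covariate, form = e$form,
           theta = e$theta, median = e$median, transform = e$transform)),
    variance = list(omega = as.list(spec$variance$omega),
                    sigma_prop = spec$variance$sigma_prop,
                    sigma_add = spec$variance$sigma_add,
                    residual_form = spec$variance$residual_form))
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- yaml::read_yaml(path)
  model_spec(
    n_compartments = x$n_compartments,
    theta = unlist(x$theta),
    effects = lapply(x$effects, function(e)
      covariate_effect(e$parameter, e$covariate, e$form, e$theta,
                       median = e$median, transform = e$transform)),
    variance = variance_model(
      omega = unlist(x$variance$omega) %||% numeric(),
      sigma_prop = x$variance$sigma_prop, sigma_add = x$variance$sigma_add,
      residual_form = x$variance$residual_form))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
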