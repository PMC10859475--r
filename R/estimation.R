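# Parameter vector layout (transformed scale) for the outer optimizer:
#   log structural thetas | covariate thetas (log for categorical form,
#   untransformed otherwise) | log omega per IIV parameter | log sigma(s).
.pack_spec <- function(spec) {
  n_str <- if (spec$n_compartments == 2) 4L else 2L
  th <- log(unname(spec$theta[seq_len(n_str)]))
  cov_log <- vapply(spec$effects, function(e) e$form == "categorical", TRUE)
  th_cov <- vapply(spec$effects, function(e) e$theta, 0)
  th_cov[cov_log] <- log(th_cov[cov_log])
  om <- spec$variance$omega
  rf <- spec$variance$residual_form
  sg <- switch(rf,
               proportional = log(spec$variance$sigma_prop),
               additive = log(spec$variance$sigma_add),
               combined = c(log(spec$variance$sigma_add),
                            log(spec$variance$sigma_prop)))
  list(par = c(th, th_cov, if (length(om)) log(unname(om)), sg),
       n_str = n_str, n_eff = length(spec$effects), cov_log = cov_log,
       n_om = length(om), rf = rf)
}

.unpack_par <- function(par, layout) {
  i <- 0L
  th <- exp(par[i + seq_len(layout$n_str)]); i <- i + layout$n_str
  th_cov <- if (layout$n_eff) par[i + seq_len(layout$n_eff)] else numeric()
  i <- i + layout$n_eff
  th_cov[layout$cov_log] <- exp(th_cov[layout$cov_log])
  om <- if (layout$n_om) exp(par[i + seq_len(layout$n_om)]) else numeric()
  i <- i + layout$n_om
  if (layout$rf == "proportional") {
    s_add <- 0; s_prop <- exp(par[i + 1L])
  } else if (layout$rf == "additive") {
    s_add <- exp(par[i + 1L]); s_prop <- 0
  } else {
    s_add <- exp(par[i + 1L]); s_prop <- exp(par[i + 2L])
  }
  list(theta = th, theta_cov = th_cov, omega = om,
       sig2_add = s_add^2, sig2_prop = s_prop^2)
}

.spec_with_par <- function(spec, up) {
  n_str <- if (spec$n_compartments == 2) 4L else 2L
  theta <- setNames(up$theta, names(spec$theta)[seq_len(n_str)])
  effects <- spec$effects
  for (e in seq_along(effects)) effects[[e]]$theta <- up$theta_cov[e]
  om <- spec$variance$omega
  if (length(om)) om[] <- up$omega
  variance <- variance_model(omega = om,
                             sigma_prop = sqrt(up$sig2_prop),
                             sigma_add = sqrt(up$sig2_add),
                             residual_form = spec$variance$residual_form)
  model_spec(spec$n_compartments, theta, effects, variance)
}

.foce_eval <- function(flat, spec, up, inner_tol = 1e-8, max_inner = 100L,
                       want_eta = FALSE) {
  theta4 <- c(up$theta, 1, 1)[1:4]
  cpp_foce(flat$obs_ptr, flat$obs_time, flat$obs_dv,
           flat$dose_ptr, flat$dose_start, flat$dose_amt, flat$dose_dur,
           theta4, as.numeric(up$theta_cov),
           as.integer(flat$eff_param), as.integer(flat$eff_form),
           flat$eff_x, as.integer(flat$eta_param),
           as.numeric(up$omega^2), up$sig2_add, up$sig2_prop,
           spec$n_compartments, inner_tol, as.integer(max_inner), want_eta)
}

#' Objective function value (FOCE-type approximate -2 log-likelihood)
#'
#' Sum over subjects of the Laplace-approximated marginal -2 log-likelihood
#' with each subject's random effects at their conditional mode and residual
#' variance evaluated at the individual predictions (interaction).
#' Deterministic given data and parameter values: the inner mode search
#' always starts from `eta = 0`.
#'
#' @param data a PK dataset (see [read_nm_csv()]).
#' @param spec a [model_spec()]; its stated theta/omega/sigma values are the
#'   evaluation point.
#' @param inner_tol convergence tolerance of the inner eta-mode search.
#' @return The OFV (numeric scalar). Per-subject contributions are attached
#'   as attribute `"ofv_i"`.
#' @export
ofv <- function(data, spec, inner_tol = 1e-8) {
  flat <- .flatten_nm(data, spec)
  layout <- .pack_spec(spec)
  up <- .unpack_par(layout$par, layout)
  res <- .foce_eval(flat, spec, up, inner_tol = inner_tol)
  if (!res$ok)
    stop("inner eta-mode search failed for subject(s): ",
         paste(flat$ids[!is.finite(res$ofv_i)], collapse = ", "))
  structure(res$ofv, ofv_i = setNames(res$ofv_i, flat$ids))
}

#' Conditional -2 log-likelihood contribution of one subject
#'
#' At a given random-effect vector `eta`: for each observation,
#' `ln(2*pi*var) + (y - f)^2/var` with `var = sigma_add^2 +
#' sigma_prop^2 * f^2` at the individual prediction `f`, plus the prior term
#' `eta' Omega^-1 eta + ln det(2*pi*Omega)`.
#'
#' @param subject_data dataset rows for one subject (doses + observations).
#' @param spec a [model_spec()].
#' @param eta named random-effect vector (names among the omega parameters);
#'   missing entries are 0.
#' @return The conditional -2 log-likelihood (numeric scalar).
#' @export
neg2ll_subject <- function(subject_data, spec, eta = numeric()) {
  if (length(unique(subject_data$ID)) != 1)
    stop("subject_data must contain exactly one subject")
  flat <- .flatten_nm(subject_data, spec)
  if (flat$n_obs < 1) stop("subject has no observations")
  typ <- model_typicals(spec, flat$first_row)
  om <- spec$variance$omega
  full_eta <- setNames(numeric(length(om)), names(om))
  if (length(eta)) {
    if (is.null(names(eta)) || !all(names(eta) %in% names(om)))
      stop("eta names must be parameters with IIV")
    full_eta[names(eta)] <- eta
  }
  p <- unlist(typ[1, ])
  p[names(om)] <- p[names(om)] * exp(full_eta)
  pp <- if (spec$n_compartments == 2)
    pk_params(p[["CL"]], p[["V1"]], p[["Q"]], p[["V2"]])
  else pk_params(p[["CL"]], p[["V1"]])
  doses <- dose_events(flat$dose_start, flat$dose_amt, flat$dose_dur)
  f <- pk_concentration(flat$obs_time, doses, pp)
  fv <- pmax(f, if (spec$variance$sigma_prop > 0) 1e-10 else -Inf)
  v <- spec$variance$sigma_add^2 + spec$variance$sigma_prop^2 * fv^2
  ll <- sum(log(2 * pi * v) + (flat$obs_dv - f)^2 / v)
  if (length(om))
    ll <- ll + sum(full_eta^2 / om^2) + sum(log(2 * pi * om^2))
  ll
}

#' Fit a population-PK model by FOCE-type estimation
#'
#' Minimizes [ofv()] over the fixed effects and variance components
#' (positive parameters log-transformed; covariate effect sizes
#' unconstrained except the categorical form). A Nelder-Mead search is
#' followed by a quasi-Newton polish; relative standard errors come from the
#' inverse Hessian at the optimum.
#'
#' @param data a PK dataset.
#' @param spec a [model_spec()]; its values are the starting point unless
#'   `initials` is supplied.
#' @param initials optional [model_spec()] (same structure) providing
#'   starting values, e.g. [generic_initials()].
#' @param estimate if `FALSE`, evaluate at the starting values only (OFV and
#'   empirical Bayes estimates, no optimization).
#' @param control list: `eval_max`/`iter_max` (per quasi-Newton round,
#'   defaults 3000/600), `restarts` (max rounds, default 3; optimization
#'   restarts while a round improves the OFV by more than `restart_tol`),
#'   `reltol` (outer relative tolerance, default 1e-10), `maxit_nm`
#'   (fallback Nelder-Mead iterations), `inner_tol` (eta-mode search,
#'   default 1e-8), `hessian` (compute RSEs, default TRUE).
#' @return An object of class `ppk_fit`: `estimates` (data.frame with
#'   natural-scale estimates and RSE%), `ofv`, `aic`
#'   (= OFV + 2 x n. estimated parameters), `ebes` (subjects x eta matrix),
#'   `spec` (the spec updated with the estimates), `converged`, `n_obs`,
#'   `n_subjects`.
#' @export
fit_ppk <- function(data, spec, initials = NULL, estimate = TRUE,
                    control = list()) {
  ctl <- modifyList(list(eval_max = 3000L, iter_max = 600L, restarts = 3L,
                         restart_tol = 0.01, maxit_nm = 2000L, reltol = 1e-10,
                         inner_tol = 1e-8, hessian = TRUE,
                         n_starts = 5L, presearch_max = 400L,
                         jitter_log = 0.4, jitter_lin = 1.0,
                         start_seed = 1001L), control)
  start_spec <- if (is.null(initials)) spec else initials
  layout <- .pack_spec(start_spec)
  flat <- .flatten_nm(data, spec)
  penalty <- 1e10
  obj <- function(par) {
    up <- .unpack_par(par, layout)
    res <- tryCatch(.foce_eval(flat, spec, up, inner_tol = ctl$inner_tol),
                    error = function(e) NULL)
    if (is.null(res) || !res$ok || !is.finite(res$ofv)) penalty else res$ofv
  }
  if (!estimate) {
    par <- layout$par
    conv <- TRUE
    counts <- 0L
  } else {
    # multi-start: the nominal initials plus deterministically jittered
    # alternatives, each given a cheap quasi-Newton pre-search; the best
    # basin is then polished. Guards against local optima of the marginal
    # likelihood (covariate effects on high-IIV parameters are multimodal).
    npar0 <- length(layout$par)
    is_log <- .par_is_log(layout)
    starts <- list(layout$par)
    if (ctl$n_starts > 1) {
      jit <- .with_local_seed(ctl$start_seed, {
        lapply(seq_len(ctl$n_starts - 1), function(s)
          rnorm(npar0, 0, ifelse(is_log, ctl$jitter_log, ctl$jitter_lin)))
      })
      starts <- c(starts, lapply(jit, function(j) layout$par + j))
    }
    counts <- 0L
    pres <- lapply(starts, function(p0) {
      o <- tryCatch(
        nlminb(p0, obj, control = list(eval.max = ctl$presearch_max,
                                       iter.max = ctl$presearch_max,
                                       rel.tol = ctl$reltol)),
        error = function(e) NULL)
      if (is.null(o)) list(par = p0, value = obj(p0), n = 1L)
      else list(par = o$par, value = o$objective, n = o$evaluations[1])
    })
    counts <- counts + sum(vapply(pres, function(x) x$n, 0))
    best_i <- which.min(vapply(pres, function(x) x$value, 0))
    par <- pres[[best_i]]$par
    val <- pres[[best_i]]$value
    conv <- FALSE
    for (round in seq_len(ctl$restarts)) {
      o <- tryCatch(
        nlminb(par, obj, control = list(eval.max = ctl$eval_max,
                                        iter.max = ctl$iter_max,
                                        rel.tol = ctl$reltol)),
        error = function(e) NULL)
      if (is.null(o)) break
      counts <- counts + o$evaluations[1]
      improved <- o$objective < val - ctl$restart_tol
      if (o$objective <= val) {
        par <- o$par
        val <- o$objective
        conv <- TRUE
      }
      if (!improved) break
    }
    if (!conv || val >= penalty) {
      o <- optim(par, obj, method = "Nelder-Mead",
                 control = list(maxit = ctl$maxit_nm, reltol = 1e-10))
      counts <- counts + o$counts[1]
      if (o$value <= val) {
        par <- o$par
        val <- o$value
      }
      conv <- val < penalty
    }
  }
  up <- .unpack_par(par, layout)
  final <- .foce_eval(flat, spec, up, inner_tol = ctl$inner_tol,
                      want_eta = TRUE)
  if (!final$ok) conv <- FALSE
  fitted_spec <- .spec_with_par(spec, up)

  npar <- length(par)
  ofv_val <- final$ofv
  aic <- ofv_val + 2 * npar

  # RSEs from the inverse Hessian of the OFV (2 x observed information)
  rse <- rep(NA_real_, npar)
  if (estimate && conv && isTRUE(ctl$hessian)) {
    H <- tryCatch(optimHess(par, obj), error = function(e) NULL)
    if (!is.null(H)) {
      cv <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(cv)) {
        se_t <- sqrt(pmax(diag(cv), 0))
        # log-scale parameters: se of log == relative se of the natural value
        is_log <- .par_is_log(layout)
        nat <- .par_natural(par, layout)
        rse <- ifelse(is_log, 100 * se_t, 100 * se_t / abs(nat))
      }
    }
  }

  est <- data.frame(name = .par_names(spec, layout), type = .par_types(layout),
                    estimate = .par_natural(par, layout), rse = rse,
                    stringsAsFactors = FALSE)
  ebes <- t(final$eta)
  if (ncol(ebes)) colnames(ebes) <- names(spec$variance$omega)
  rownames(ebes) <- as.character(flat$ids)

  structure(list(estimates = est, ofv = ofv_val, aic = aic, npar = npar,
                 ebes = ebes, spec = fitted_spec, start_spec = start_spec,
                 converged = conv, n_obs = flat$n_obs,
                 n_subjects = flat$n_subj, n_eval = counts),
            class = "ppk_fit")
}

.par_is_log <- function(layout) {
  npar <- layout$n_str + layout$n_eff + layout$n_om +
    if (layout$rf == "combined") 2L else 1L
  is_log <- rep(TRUE, npar)
  cov_idx <- layout$n_str + seq_len(layout$n_eff)
  is_log[cov_idx[!layout$cov_log]] <- FALSE
  is_log
}

# evaluate expr under a fixed local RNG seed, restoring the caller's RNG state
.with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.par_natural <- function(par, layout) {
  up <- .unpack_par(par, layout)
  sg <- if (layout$rf == "proportional") sqrt(up$sig2_prop)
  else if (layout$rf == "additive") sqrt(up$sig2_add)
  else c(sqrt(up$sig2_add), sqrt(up$sig2_prop))
  c(up$theta, up$theta_cov, up$omega, sg)
}

.par_names <- function(spec, layout) {
  eff_nm <- vapply(spec$effects, function(e)
    paste0("theta_", e$covariate, "-", e$parameter), "")
  om_nm <- if (layout$n_om) paste0("omega_", names(spec$variance$omega)) else character()
  sg_nm <- switch(layout$rf, proportional = "sigma_prop",
                  additive = "sigma_add",
                  combined = c("sigma_add", "sigma_prop"))
  c(names(spec$theta)[seq_len(layout$n_str)], eff_nm, om_nm, sg_nm)
}

.par_types <- function(layout) {
  c(rep("theta", layout$n_str), rep("theta_cov", layout$n_eff),
    rep("omega", layout$n_om),
    rep("sigma", if (layout$rf == "combined") 2L else 1L))
}

#' Generic starting values for estimation
#'
#' Neutral initials detached from any published estimate: structural thetas
#' at round mid-range values, covariate effects at weak defaults (linear 1,
#' power 0.5, exponential 0.1, categorical 1), all omegas at 30% and the
#' residual sd at 10%.
#'
#' @param spec a [model_spec()] defining the structure.
#' @return A [model_spec()] with the same structure and generic values.
#' @export
generic_initials <- function(spec) {
  theta <- spec$theta
  defaults <- c(CL = 5, V1 = 40, Q = 30, V2 = 100)
  theta[] <- defaults[names(theta)]
  effects <- lapply(spec$effects, function(e) {
    e$theta <- switch(e$form, linear = 1, power = 0.5, exponential = 0.1,
                      categorical = 1)
    e
  })
  om <- spec$variance$omega
  if (length(om)) om[] <- 0.3
  rf <- spec$variance$residual_form
  variance <- variance_model(omega = om,
                             sigma_prop = if (rf != "additive") 0.1 else 0,
                             sigma_add = if (rf != "proportional") 0.5 else 0,
                             residual_form = rf)
  model_spec(spec$n_compartments, theta, effects, variance)
}

#' @export
print.ppk_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<ppk_fit> %s | %d subjects, %d observations\n",
              if (x$converged) "converged" else "NOT CONVERGED",
              x$n_subjects, x$n_obs))
  cat(sprintf("  OFV = %.3f, AIC = %.3f (%d estimated parameters)\n",
              x$ofv, x$aic, x$npar))
  est <- x$estimates
  est$estimate <- signif(est$estimate, digits)
  est$rse <- signif(est$rse, 3)
  # report omega/sigma on the conventional percent scale
  pct <- est$type %in% c("omega", "sigma")
  est$estimate[pct] <- sd_to_pct(est$estimate[pct])
  est$name[pct] <- paste0(est$name[pct], "_pct")
  print(est, row.names = FALSE)
  invisible(x)
}

#' Extract a coefficient table from a fit
#'
#' @param object a `ppk_fit`.
#' @param ... unused.
#' @return The `estimates` data.frame.
#' @export
coef.ppk_fit <- function(object, ...) object$estimates
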