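#' Structural PK parameters
#'
#' Container for the disposition parameters of the two-compartment model
#' (clearance `CL`, central volume `V1`, intercompartmental clearance `Q`,
#' peripheral volume `V2`). A one-compartment parameter set omits `Q`/`V2`.
#'
#' @param CL clearance (L/h), strictly positive.
#' @param V1 central volume of distribution (L), strictly positive.
#' @param Q intercompartmental clearance (L/h); `NULL` for one-compartment.
#' @param V2 peripheral volume of distribution (L); `NULL` for one-compartment.
#' @return An object of class `pk_params` (named numeric vector with an
#'   `ncmt` attribute).
#' @examples
#' pk_params(CL = 6.37, V1 = 32.1, Q = 39.7, V2 = 113)
#' @export
pk_params <- function(CL, V1, Q = NULL, V2 = NULL) {
  one_cmt <- is.null(Q) && is.null(V2)
  if (!one_cmt && (is.null(Q) || is.null(V2)))
    stop("supply both Q and V2 (two-compartment) or neither (one-compartment)")
  p <- if (one_cmt) c(CL = CL, V1 = V1) else c(CL = CL, V1 = V1, Q = Q, V2 = V2)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("invalid PK parameters: all must be finite and strictly positive")
  structure(p, ncmt = if (one_cmt) 1L else 2L, class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("<pk_params> %d-compartment\n", attr(x, "ncmt")))
  print(unclass(x)[seq_along(x)])
  invisible(x)
}

.as_p4 <- function(params) {
  # internal: always length-4 vector (CL, V1, Q, V2) + ncmt
  ncmt <- attr(params, "ncmt")
  if (is.null(ncmt)) ncmt <- if (length(params) >= 4L) 2L else 1L
  p <- unclass(params)
  if (ncmt == 1L) p <- c(p[["CL"]], p[["V1"]], 1, 1)
  else p <- c(p[["CL"]], p[["V1"]], p[["Q"]], p[["V2"]])
  list(p = p, ncmt = as.integer(ncmt))
}

#' Dose events
#'
#' One row per administration: start time (h since first dose), amount (mg)
#' and zero-order infusion duration (h; the study design infuses over 30 min).
#'
#' @param start_time start of infusion, hours since first dose (>= 0).
#' @param amount dose amount in mg (> 0).
#' @param infusion_duration infusion length in hours (> 0); default 0.5.
#' @return A `data.frame` with columns `start_time`, `amount`,
#'   `infusion_duration`.
#' @examples
#' dose_events(start_time = c(0, 12), amount = c(100, 50))
#' @export
dose_events <- function(start_time, amount, infusion_duration = 0.5) {
  d <- data.frame(start_time = start_time, amount = amount,
                  infusion_duration = infusion_duration)
  if (nrow(d) == 0) stop("dose history must be non-empty")
  if (any(d$amount <= 0)) stop("dose amount must be > 0")
  if (any(d$infusion_duration <= 0)) stop("infusion_duration must be > 0")
  if (any(d$start_time < 0)) stop("start_time must be >= 0")
  d
}

#' Dosing regimen
#'
#' A maintenance dose given every `interval` hours as a short infusion, with
#' an optional distinct loading (first) dose, e.g. the label regimen
#' 100 mg followed by 50 mg every 12 h.
#'
#' @param maintenance_dose maintenance dose (mg).
#' @param interval dosing interval (h), > 0.
#' @param loading_dose optional first dose (mg); `NULL` for none.
#' @param infusion_duration infusion length (h), default 0.5.
#' @param n_doses number of administrations (>= 1).
#' @return An object of class `regimen`.
#' @examples
#' regimen(50, loading_dose = 100)
#' @export
regimen <- function(maintenance_dose, interval = 12, loading_dose = NULL,
                    infusion_duration = 0.5, n_doses = 20L) {
  if (interval <= 0) stop("interval must be > 0")
  if (n_doses < 1) stop("n_doses must be >= 1")
  if (maintenance_dose <= 0) stop("maintenance_dose must be > 0")
  structure(list(maintenance_dose = maintenance_dose, interval = interval,
                 loading_dose = loading_dose,
                 infusion_duration = infusion_duration,
                 n_doses = as.integer(n_doses)),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  ld <- if (is.null(x$loading_dose)) "none" else sprintf("%g mg", x$loading_dose)
  cat(sprintf("<regimen> %g mg q%gh (loading: %s), %g-h infusion, %d doses\n",
              x$maintenance_dose, x$interval, ld, x$infusion_duration,
              x$n_doses))
  invisible(x)
}

#' Expand a regimen into explicit dose events
#'
#' @param reg a [regimen()].
#' @param n_doses optional override of the number of doses.
#' @return A dose-event `data.frame` as from [dose_events()].
#' @export
regimen_doses <- function(reg, n_doses = NULL) {
  stopifnot(inherits(reg, "regimen"))
  n <- if (is.null(n_doses)) reg$n_doses else as.integer(n_doses)
  amt <- rep(reg$maintenance_dose, n)
  if (!is.null(reg$loading_dose)) amt[1] <- reg$loading_dose
  dose_events(start_time = (seq_len(n) - 1) * reg$interval, amount = amt,
              infusion_duration = reg$infusion_duration)
}

#' Micro rate constants and hybrid constants of the two-compartment model
#'
#' Computes `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2` and the hybrid
#' disposition constants `alpha`, `beta` (the roots of
#' `s^2 - (k10+k12+k21) s + k10*k21 = 0`, `alpha >= beta > 0`).
#'
#' @param params a two-compartment [pk_params()].
#' @return Named numeric vector `k10, k12, k21, alpha, beta` (all 1/h).
#' @examples
#' microconstants(pk_params(6.37, 32.1, 39.7, 113))
#' @export
microconstants <- function(params) {
  if (!inherits(params, "pk_params")) params <- do.call(pk_params, as.list(params))
  if (attr(params, "ncmt") != 2L)
    stop("microconstants are defined for the two-compartment model")
  k10 <- params[["CL"]] / params[["V1"]]
  k12 <- params[["Q"]] / params[["V1"]]
  k21 <- params[["Q"]] / params[["V2"]]
  s <- k10 + k12 + k21
  root <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + root) / 2
  beta <- (s - root) / 2
  if ((alpha - beta) <= 1e-10 * alpha)
    stop("degenerate two-compartment roots (alpha ~ beta within 1e-10 relative)")
  c(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta)
}

#' Plasma concentration under a dosing history
#'
#' Analytic central-compartment concentration for zero-order infusions with
#' first-order elimination, superposed over all doses (the model is linear in
#' dose amounts). Piecewise during-/post-infusion branches are continuous at
#' the end of each infusion.
#'
#' @param t time(s) since first dose (h), >= 0; vectorized.
#' @param doses a dose-event `data.frame` ([dose_events()] or
#'   [regimen_doses()]).
#' @param params a [pk_params()].
#' @return Concentration(s) in mg/L.
#' @examples
#' p <- pk_params(6.37, 32.1, 39.7, 113)
#' pk_concentration(c(0.5, 1, 6), dose_events(0, 100), p)
#' @export
pk_concentration <- function(t, doses, params) {
  if (any(t < 0)) stop("time must be >= 0")
  if (!is.data.frame(doses) || nrow(doses) == 0)
    stop("doses must be a non-empty dose-event data.frame")
  if (!inherits(params, "pk_params")) params <- do.call(pk_params, as.list(params))
  pp <- .as_p4(params)
  cpp_conc(as.numeric(t), doses$start_time, doses$amount,
           doses$infusion_duration, pp$p[1], pp$p[2], pp$p[3], pp$p[4],
           pp$ncmt)
}

#' Linear trapezoidal AUC
#'
#' Linear-up/linear-down trapezoidal rule: the linear trapezoid is applied on
#' both rising and falling segments.
#'
#' @param times strictly increasing sampling times (h), length >= 2.
#' @param concs non-negative concentrations (mg/L), same length.
#' @return AUC in mg*h/L.
#' @examples
#' auc_trapezoid(c(0, 1, 2), c(0, 2, 0))  # 2
#' @export
auc_trapezoid <- function(times, concs) {
  if (length(times) != length(concs) || length(times) < 2)
    stop("times and concs must have equal length >= 2")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(concs < 0)) stop("concs must be non-negative")
  sum(diff(times) * (head(concs, -1) + tail(concs, -1)) / 2)
}

#' Steady-state AUC over 24 hours
#'
#' AUC(0-24) at steady state for a repeated-dose regimen, either by explicit
#' superposition of prior doses and dense trapezoidal integration over one
#' dosing interval (default; also exact for sampling at a finite dose number),
#' or by the analytic identity AUC24 = daily dose / CL.
#'
#' @param reg a [regimen()].
#' @param params a [pk_params()].
#' @param method `"superposition"` (trapezoid over the interval after >= 20
#'   doses) or `"analytic"` (daily dose / CL).
#' @param dt time step (h) of the trapezoid grid, default 0.05.
#' @param min_doses minimum number of prior doses for the superposition
#'   method (accumulation has converged well before 20 given the terminal
#'   slope magnitudes here).
#' @return AUC over 24 h at steady state, mg*h/L. The per-interval AUC is
#'   attached as attribute `"auc_tau"`.
#' @examples
#' p <- pk_params(6.37, 32.1, 39.7, 113)
#' steady_state_auc24(regimen(50), p, method = "analytic")  # 100/6.37
#' @export
steady_state_auc24 <- function(reg, params,
                               method = c("superposition", "analytic"),
                               dt = 0.05, min_doses = 20L) {
  method <- match.arg(method)
  stopifnot(inherits(reg, "regimen"))
  if (!inherits(params, "pk_params")) params <- do.call(pk_params, as.list(params))
  daily <- reg$maintenance_dose * 24 / reg$interval
  if (method == "analytic") {
    auc24 <- daily / params[["CL"]]
    attr(auc24, "auc_tau") <- auc24 * reg$interval / 24
    return(auc24)
  }
  n <- max(reg$n_doses, min_doses)
  doses <- regimen_doses(reg, n_doses = n)
  t0 <- (n - 1) * reg$interval
  grid <- seq(t0, t0 + reg$interval, by = dt)
  if (tail(grid, 1) < t0 + reg$interval) grid <- c(grid, t0 + reg$interval)
  cc <- pk_concentration(grid, doses, params)
  auc_tau <- auc_trapezoid(grid, pmax(cc, 0))
  auc24 <- auc_tau * 24 / reg$interval
  attr(auc24, "auc_tau") <- auc_tau
  auc24
}
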