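#' Covariate correlation pre-screen
#'
#' Pairwise Spearman correlations between per-subject covariate values;
#' pairs exceeding the cutoff in absolute value are flagged so that both
#' members are not allowed to co-enter a model during forward inclusion.
#'
#' @param data a PK dataset.
#' @param covariates character vector of covariate column names.
#' @param cutoff absolute Spearman correlation cutoff, default 0.5.
#' @return A `data.frame` with columns `cov1`, `cov2`, `rho`, `flagged`.
#' @export
covariate_screen <- function(data, covariates, cutoff = 0.5) {
  miss <- setdiff(covariates, names(data))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  first <- data[!duplicated(data$ID), covariates, drop = FALSE]
  out <- data.frame()
  if (length(covariates) >= 2) {
    cm <- suppressWarnings(cor(first, method = "spearman"))
    idx <- which(upper.tri(cm), arr.ind = TRUE)
    out <- data.frame(cov1 = covariates[idx[, 1]], cov2 = covariates[idx[, 2]],
                      rho = cm[idx], stringsAsFactors = FALSE)
    out$flagged <- !is.na(out$rho) & abs(out$rho) > cutoff
  }
  out
}

.conflicts <- function(candidate, included_covs, screen) {
  if (is.null(screen) || !nrow(screen)) return(FALSE)
  fl <- screen[screen$flagged, , drop = FALSE]
  any((fl$cov1 == candidate$covariate & fl$cov2 %in% included_covs) |
      (fl$cov2 == candidate$covariate & fl$cov1 %in% included_covs))
}

#' Forward inclusion of covariate effects
#'
#' Greedy stepwise search: at each step every remaining candidate is added
#' to the current model and refitted; the candidate with the largest OFV
#' decrease is included if the decrease is at least `threshold` (default
#' 3.84, chi-square p < 0.05 with 1 df). Ties are broken by candidate list
#' order. Candidates whose covariate is correlation-flagged against an
#' already-included covariate are skipped, as are candidates whose refit
#' fails (both logged).
#'
#' @param data a PK dataset.
#' @param base a [model_spec()] to start from.
#' @param candidates list of [covariate_effect()]s to consider.
#' @param threshold minimum OFV decrease for inclusion (>= semantics).
#' @param screen optional result of [covariate_screen()].
#' @param control passed to [fit_ppk()].
#' @return A list with `spec` (selected model), `fit` (its fit), and `log`
#'   (a data.frame recording every tested delta-OFV).
#' @export
forward_inclusion <- function(data, base, candidates, threshold = 3.84,
                              screen = NULL, control = list()) {
  current <- base
  fit <- fit_ppk(data, current, control = control)
  log <- data.frame()
  step <- 0L
  remaining <- candidates
  repeat {
    step <- step + 1L
    best <- NULL
    best_delta <- -Inf
    deltas <- rep(NA_real_, length(remaining))
    included_covs <- vapply(current$effects, function(e) e$covariate, "")
    for (i in seq_along(remaining)) {
      cand <- remaining[[i]]
      status <- "tested"
      if (.conflicts(cand, included_covs, screen)) {
        status <- "skipped_correlated"
      } else {
        cand_fit <- tryCatch(
          fit_ppk(data, spec_add_effect(current, cand), control = control),
          error = function(e) NULL)
        if (is.null(cand_fit) || !cand_fit$converged) {
          status <- "skipped_fit_failure"
        } else {
          deltas[i] <- fit$ofv - cand_fit$ofv
          if (deltas[i] > best_delta) {
            best_delta <- deltas[i]
            best <- list(idx = i, fit = cand_fit)
          }
        }
      }
      log <- rbind(log, data.frame(
        step = step, action = "forward",
        parameter = cand$parameter, covariate = cand$covariate,
        delta_ofv = deltas[i], status = status, stringsAsFactors = FALSE))
    }
    if (is.null(best) || best_delta < threshold) break
    log$status[nrow(log) - length(remaining) + best$idx] <- "included"
    # carry the estimates forward as the next step's starting point
    current <- best$fit$spec
    fit <- best$fit
    remaining <- remaining[-best$idx]
    if (!length(remaining)) break
  }
  list(spec = current, fit = fit, log = log)
}

#' Backward elimination of covariate effects
#'
#' Iteratively refits the model with each effect removed; the effect whose
#' removal increases the OFV the least is eliminated whenever that increase
#' is at most `threshold` (default 10.83, chi-square p < 0.001 with 1 df).
#' Every retained effect therefore has a removal cost strictly greater than
#' the threshold.
#'
#' @param data a PK dataset.
#' @param full a [model_spec()] (typically the forward-selected model).
#' @param threshold maximum OFV increase that still allows removal.
#' @param removable optional subset of effects eligible for removal, as a
#'   list of `c(parameter, covariate)` pairs; default all effects.
#' @param control passed to [fit_ppk()].
#' @return A list with `spec`, `fit` and `log` as in [forward_inclusion()].
#' @export
backward_elimination <- function(data, full, threshold = 10.83,
                                 removable = NULL, control = list()) {
  current <- full
  fit <- fit_ppk(data, current, control = control)
  log <- data.frame()
  step <- 0L
  is_removable <- function(e) {
    if (is.null(removable)) return(TRUE)
    any(vapply(removable, function(r)
      r[1] == e$parameter && r[2] == e$covariate, TRUE))
  }
  repeat {
    step <- step + 1L
    effs <- Filter(is_removable, current$effects)
    if (!length(effs)) break
    best <- NULL
    best_inc <- Inf
    for (e in effs) {
      red <- spec_drop_effect(current, e$parameter, e$covariate)
      red_fit <- tryCatch(fit_ppk(data, red, control = control),
                          error = function(e) NULL)
      inc <- if (is.null(red_fit) || !red_fit$converged) NA_real_
      else red_fit$ofv - fit$ofv
      log <- rbind(log, data.frame(
        step = step, action = "backward", parameter = e$parameter,
        covariate = e$covariate, delta_ofv = inc,
        status = if (is.na(inc)) "skipped_fit_failure" else "tested",
        stringsAsFactors = FALSE))
      if (!is.na(inc) && inc < best_inc) {
        best_inc <- inc
        best <- list(eff = e, fit = red_fit)
      }
    }
    if (is.null(best) || best_inc > threshold) break
    log$status[log$step == step & log$parameter == best$eff$parameter &
               log$covariate == best$eff$covariate] <- "removed"
    current <- best$fit$spec
    fit <- best$fit
  }
  list(spec = current, fit = fit, log = log)
}

#' Full stepwise covariate selection
#'
#' [forward_inclusion()] followed by [backward_elimination()] restricted to
#' the forward-selected effects, at the conventional 3.84 / 10.83 OFV
#' thresholds.
#'
#' @inheritParams forward_inclusion
#' @param forward_threshold,backward_threshold OFV thresholds.
#' @return A list with `spec`, `fit`, `forward_log`, `backward_log`.
#' @export
select_covariates <- function(data, base, candidates,
                              forward_threshold = 3.84,
                              backward_threshold = 10.83,
                              screen = NULL, control = list()) {
  fw <- forward_inclusion(data, base, candidates,
                          threshold = forward_threshold, screen = screen,
                          control = control)
  added <- lapply(fw$spec$effects, function(e) c(e$parameter, e$covariate))
  base_keys <- vapply(base$effects, function(e)
    paste(e$parameter, e$covariate), "")
  added <- Filter(function(r) !paste(r[1], r[2]) %in% base_keys, added)
  if (!length(added))
    return(list(spec = fw$spec, fit = fw$fit, forward_log = fw$log,
                backward_log = data.frame()))
  bw <- backward_elimination(data, fw$spec, threshold = backward_threshold,
                             removable = added, control = control)
  list(spec = bw$spec, fit = bw$fit, forward_log = fw$log,
       backward_log = bw$log)
}
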