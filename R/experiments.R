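#' Simulation-reestimation experiment for the final model
#'
#' Generates replicate synthetic cohorts under the published final model
#' (study design: 98 subjects, 8 samples each) and refits the final model to
#' each from neutral starting values, summarizing every parameter by its
#' median across replicates. This is the package's core validation
#' experiment: with the estimation machinery working, the medians must
#' recover the generating values.
#'
#' @param seeds integer vector of cohort seeds (one replicate per seed).
#' @param n_subjects cohort size per replicate (default 98).
#' @param spec generating/estimated model, default
#'   [tigecycline_final_model()].
#' @param control passed to [fit_ppk()] (RSEs are skipped by default here).
#' @param quiet suppress per-replicate progress messages.
#' @return A list with `estimates` (replicates x parameters matrix),
#'   `medians` (named vector), `converged` (logical per replicate),
#'   `seeds`.
#' @export
simulation_reestimation <- function(seeds = 1:5, n_subjects = 98L,
                                    spec = tigecycline_final_model(),
                                    control = list(hessian = FALSE),
                                    quiet = FALSE) {
  rows <- list()
  conv <- logical(length(seeds))
  for (i in seq_along(seeds)) {
    d <- generate_dataset(cohort_config(n_subjects = n_subjects,
                                        seed = seeds[i], spec = spec))
    t0 <- Sys.time()
    fit <- fit_ppk(d, spec, initials = generic_initials(spec),
                   control = control)
    conv[i] <- fit$converged
    rows[[i]] <- setNames(fit$estimates$estimate, fit$estimates$name)
    if (!quiet)
      message(sprintf("replicate %d/%d (seed %d): OFV %.2f, %.0f s%s",
                      i, length(seeds), seeds[i], fit$ofv,
                      as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      if (fit$converged) "" else " [not converged]"))
  }
  est <- do.call(rbind, rows)
  list(estimates = est, medians = apply(est, 2, median), converged = conv,
       seeds = seeds)
}

#' Covariate selection-power experiment
#'
#' Replicated forward-inclusion/backward-elimination runs on synthetic data
#' carrying one strong true covariate effect (body weight on V1, power
#' exponent 1.95) and one null covariate (ALT, sampled independently of the
#' PK parameters). Success in a replicate means the selected set is exactly
#' the true one: the body-weight effect included and retained, the null
#' covariate excluded. The default design is scaled down (32 subjects,
#' moderate V1 variability) so the experiment probes the stepwise machinery
#' rather than the statistical power of the full study.
#'
#' @param n_replicates number of replicate datasets.
#' @param n_subjects subjects per replicate.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param omega_v1 generating IIV standard deviation on V1.
#' @param control passed to [fit_ppk()]; defaults keep each fit cheap.
#' @param quiet suppress progress messages.
#' @return A list with `success` (logical per replicate), `selected`
#'   (character vector of selected covariate sets), `n_success`.
#' @export
selection_power_experiment <- function(n_replicates = 20L, n_subjects = 32L,
                                       seed = 100L, omega_v1 = 0.4,
                                       control = list(
                                         n_starts = 2L, presearch_max = 150L,
                                         eval_max = 400L, iter_max = 150L,
                                         restarts = 1L, hessian = FALSE),
                                       quiet = FALSE) {
  gen <- model_spec(
    2, c(CL = 3.09, V1 = 32.1, Q = 39.7, V2 = 113),
    list(covariate_effect("V1", "WT", "power", theta = 1.95, median = 61)),
    variance_model(c(CL = 0.27, V1 = omega_v1), sigma_prop = 0.0202))
  base <- model_spec(
    2, c(CL = 3.09, V1 = 32.1, Q = 39.7, V2 = 113),
    variance = variance_model(c(CL = 0.27, V1 = omega_v1),
                              sigma_prop = 0.0202))
  cands <- list(
    covariate_effect("V1", "WT", "power", theta = 0.5, median = 61),
    covariate_effect("V1", "ALT", "power", theta = 0.1, median = 19))
  success <- logical(n_replicates)
  selected <- character(n_replicates)
  for (r in seq_len(n_replicates)) {
    d <- generate_dataset(cohort_config(n_subjects = n_subjects,
                                        seed = seed + r, spec = gen))
    sel <- select_covariates(d, base, cands, control = control)
    covs <- sort(vapply(sel$spec$effects, function(e) e$covariate, ""))
    selected[r] <- paste(covs, collapse = "+")
    success[r] <- identical(covs, "WT")
    if (!quiet)
      message(sprintf("replicate %d/%d: selected {%s}%s", r, n_replicates,
                      selected[r], if (success[r]) "" else " [MISS]"))
  }
  list(success = success, selected = selected, n_success = sum(success))
}
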