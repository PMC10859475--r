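#' PK/PD targets (AUC/MIC ratios) by indication
#'
#' The AUC(0-24)/MIC efficacy thresholds used for tigecycline:
#' 6.96 for complicated intra-abdominal infection (cIAI), 12.8 for
#' community-acquired bacterial pneumonia (CAP), 17.9 for complicated skin
#' and skin structure infection (cSSSI).
#'
#' @param name `"cIAI"`, `"CAP"` or `"cSSSI"`, or a custom name with
#'   `ratio` supplied.
#' @param ratio AUC/MIC threshold; defaults to the named indication's value.
#' @return An object of class `pkpd_target` (list with `name`, `ratio`).
#' @export
pkpd_target <- function(name, ratio = NULL) {
  known <- c(cIAI = 6.96, CAP = 12.8, cSSSI = 17.9)
  if (is.null(ratio)) {
    if (!name %in% names(known))
      stop("unknown target name; supply ratio explicitly")
    ratio <- known[[name]]
  }
  if (ratio <= 0) stop("target ratio must be > 0")
  structure(list(name = name, ratio = ratio), class = "pkpd_target")
}

#' Cohort median covariates of the study population
#'
#' Median covariate values used to pin the non-varied covariates of a
#' simulation stratum: CCr 77 mL/min, BW 61 kg, GGT 10^1.7 U/L,
#' TBIL 10^1.2 umol/L, ALB 10^1.4 g/L (the model's stored normalization
#' constants, so the typical patient reproduces the published typical
#' parameter values exactly).
#'
#' @return Named numeric vector of covariates.
#' @export
reference_covariates <- function() {
  c(CCR = 77, WT = 61, GGT = 10^1.7, TBIL = 10^1.2, ALB = 10^1.4)
}

#' Liver-function stratum covariates
#'
#' `"normal"` uses the reference medians; `"abnormal"` means TBIL above
#' twice its upper limit of normal or GGT above three times its ULN.
#' Defaults: TBIL ULN 21 umol/L, GGT ULN 60 U/L, with the abnormal stratum
#' placed at 2.5x and 3.5x ULN respectively (configurable).
#'
#' @param status `"normal"` or `"abnormal"`.
#' @param tbil_uln,ggt_uln upper limits of normal.
#' @return Named covariate overrides (TBIL, GGT).
#' @export
liver_stratum <- function(status = c("normal", "abnormal"),
                          tbil_uln = 21, ggt_uln = 60) {
  status <- match.arg(status)
  if (status == "normal")
    return(reference_covariates()[c("TBIL", "GGT")])
  c(TBIL = 2.5 * tbil_uln, GGT = 3.5 * ggt_uln)
}

#' Simulate a cohort of virtual patients at a covariate stratum
#'
#' Typical parameters from the model at the stratum covariates,
#' individualized with independent `eta ~ N(0, omega^2)` per parameter
#' carrying IIV. Reproducible under `seed`.
#'
#' @param n number of virtual patients (>= 1).
#' @param stratum named covariate overrides (e.g. `c(CCR = 80)`); unnamed
#'   covariates are pinned at [reference_covariates()]. With
#'   `couple_bw_ccr = TRUE`, a `WT` override also refeeds Cockcroft-Gault
#'   (age 63.4 y, male, SCr 64 umol/L) to recompute `CCR`; decoupled by
#'   default.
#' @param spec model; default [tigecycline_final_model()].
#' @param seed RNG seed.
#' @param couple_bw_ccr couple body weight into CCr via Cockcroft-Gault.
#' @return A `data.frame` of individual parameters (columns CL, V1, Q, V2),
#'   with the stratum covariates attached as attribute `"covariates"`.
#' @export
simulate_cohort <- function(n, stratum = c(), spec = tigecycline_final_model(),
                            seed = NULL, couple_bw_ccr = FALSE) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cov <- reference_covariates()
  if (length(stratum)) cov[names(stratum)] <- stratum
  if (couple_bw_ccr && "WT" %in% names(stratum))
    cov[["CCR"]] <- cockcroft_gault(63.4, cov[["WT"]], 64, "male")
  typ <- unlist(model_typicals(spec, as.data.frame(as.list(cov)))[1, ])
  om <- spec$variance$omega
  out <- matrix(rep(typ, each = n), nrow = n,
                dimnames = list(NULL, names(typ)))
  for (nm in names(om))
    out[, nm] <- out[, nm] * exp(rnorm(n, 0, om[[nm]]))
  out <- as.data.frame(out)
  attr(out, "covariates") <- cov
  out
}

#' Probability of target attainment for a cohort and regimen
#'
#' Fraction of virtual patients whose steady-state AUC(0-24)/MIC meets the
#' target ratio. The AUC is the analytic steady-state identity
#' `daily dose / CL_individual` by default, with the trapezoidal
#' superposition pipeline available as a cross-check.
#'
#' @param cohort a [simulate_cohort()] result (data.frame with CL, V1, Q,
#'   V2).
#' @param reg a [regimen()].
#' @param mic minimum inhibitory concentration, mg/L (> 0).
#' @param target a [pkpd_target()].
#' @param auc_method `"analytic"` (default) or `"superposition"`.
#' @return PTA as a fraction in `[0, 1]`.
#' @export
pta <- function(cohort, reg, mic, target, auc_method = c("analytic",
                                                         "superposition")) {
  auc_method <- match.arg(auc_method)
  if (!nrow(cohort)) stop("empty cohort")
  if (mic <= 0) stop("MIC must be > 0")
  stopifnot(inherits(target, "pkpd_target"))
  auc24 <- if (auc_method == "analytic") {
    reg$maintenance_dose * 24 / reg$interval / cohort$CL
  } else {
    vapply(seq_len(nrow(cohort)), function(i)
      as.numeric(steady_state_auc24(
        reg, pk_params(cohort$CL[i], cohort$V1[i], cohort$Q[i],
                       cohort$V2[i]))), 0)
  }
  mean(auc24 / mic >= target$ratio)
}

.derive_seed <- function(master, k) {
  # deterministic per-cell seed below 2^31
  as.integer((as.numeric(master) * 48271 + k * 1000003) %% 2147483587) + 1L
}

#' PTA grid over regimens, MICs, strata and targets
#'
#' Full cross-product Monte Carlo PTA surface: for each cell a cohort of
#' `n` virtual patients is simulated at the stratum covariates and the PTA
#' computed. Per-cell seeds derive deterministically from `seed`, so cells
#' are independent but the grid is reproducible; with
#' `common_random_numbers = TRUE` every cell of the same stratum shares one
#' cohort (useful for dose-monotonicity comparisons).
#'
#' @param regimens named list of [regimen()]s (e.g. standard / high dose).
#' @param mics MIC grid (mg/L), default `c(0.125, 0.25, 0.5, 1, 2, 4, 8)`.
#' @param strata a `data.frame` with columns `family`, `value` (e.g.
#'   family `"CCr"` values 30/80/130; `"BW"` 40/60/80/100; `"liver"`
#'   normal/abnormal), or `NULL` for the reference stratum only.
#' @param targets list of [pkpd_target()]s.
#' @param n virtual patients per cell (default 1000, as in the design).
#' @param seed master seed.
#' @param spec model; default [tigecycline_final_model()].
#' @param common_random_numbers share cohorts across regimens/MICs/targets.
#' @param couple_bw_ccr see [simulate_cohort()].
#' @return An object of class `pta_grid`: long `data.frame` with columns
#'   `regimen`, `mic`, `family`, `value`, `target`, `pta`, `n`, `seed`.
#' @export
pta_grid <- function(regimens = list(std_50mg_q12h = regimen(50, loading_dose = 100),
                                     high_100mg_q12h = regimen(100, loading_dose = 200)),
                     mics = c(0.125, 0.25, 0.5, 1, 2, 4, 8),
                     strata = NULL,
                     targets = list(pkpd_target("cIAI"), pkpd_target("CAP"),
                                    pkpd_target("cSSSI")),
                     n = 1000L, seed = 1L, spec = tigecycline_final_model(),
                     common_random_numbers = FALSE, couple_bw_ccr = FALSE) {
  if (is.null(strata))
    strata <- data.frame(family = "reference", value = "median",
                         stringsAsFactors = FALSE)
  rows <- list()
  cell <- 0L
  for (s in seq_len(nrow(strata))) {
    fam <- strata$family[s]
    val <- strata$value[s]
    stratum <- switch(fam,
      CCr = c(CCR = as.numeric(val)),
      BW = c(WT = as.numeric(val)),
      liver = liver_stratum(as.character(val)),
      reference = c(),
      stop("unknown stratum family: ", fam))
    cohort_crn <- NULL
    seed_crn <- NA_integer_
    if (common_random_numbers) {
      seed_crn <- .derive_seed(seed, s)
      cohort_crn <- simulate_cohort(n, stratum, spec, seed = seed_crn,
                                    couple_bw_ccr = couple_bw_ccr)
    }
    for (rg in names(regimens)) for (mic in mics) for (tg in targets) {
      cell <- cell + 1L
      if (common_random_numbers) {
        co <- cohort_crn
        sd_i <- seed_crn
      } else {
        sd_i <- .derive_seed(seed, cell)
        co <- simulate_cohort(n, stratum, spec, seed = sd_i,
                              couple_bw_ccr = couple_bw_ccr)
      }
      rows[[cell]] <- data.frame(
        regimen = rg, mic = mic, family = fam, value = as.character(val),
        target = tg$name, pta = pta(co, regimens[[rg]], mic, tg),
        n = n, seed = sd_i, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "regimens") <- regimens
  class(out) <- c("pta_grid", class(out))
  out
}

#' Recommend the lowest sufficient regimen per grid cell
#'
#' For each (MIC, stratum, target) combination, the regimen with the lowest
#' daily dose whose PTA meets the threshold (default 90%); `"none
#' attainable"` where no regimen qualifies.
#'
#' @param grid a [pta_grid()].
#' @param threshold PTA criterion, default 0.9.
#' @return A `data.frame` with columns `mic`, `family`, `value`, `target`,
#'   `recommended`, `pta`.
#' @export
recommend_regimen <- function(grid, threshold = 0.9) {
  stopifnot(inherits(grid, "pta_grid"))
  regs <- attr(grid, "regimens")
  daily <- vapply(regs, function(r) r$maintenance_dose * 24 / r$interval, 0)
  ord <- names(sort(daily))
  key <- interaction(grid$mic, grid$family, grid$value, grid$target,
                     drop = TRUE)
  out <- lapply(split(grid, key), function(d) {
    rec <- NA_character_
    pv <- NA_real_
    for (rg in ord) {
      p <- d$pta[d$regimen == rg]
      if (length(p) && p[1] >= threshold) {
        rec <- rg
        pv <- p[1]
        break
      }
    }
    data.frame(mic = d$mic[1], family = d$family[1], value = d$value[1],
               target = d$target[1],
               recommended = if (is.na(rec)) "none attainable" else rec,
               pta = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$family, out$value, out$target, out$mic), ]
}
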