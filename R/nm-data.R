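#' Read and write longitudinal PK datasets (NONMEM-dialect CSV)
#'
#' One row per event: `ID`, `TIME` (h), `EVID` (1 = dose, 0 = observation),
#' `AMT` (mg, dose rows), `RATE` (mg/h, dose rows; infusion duration is
#' `AMT/RATE`), `DV` (mg/L, observation rows), `MDV`, plus uppercase
#' covariate columns (`AGE`, `SEX`, `WT`, `SCR`, `CCR`, `ALB`, `GGT`,
#' `TBIL`, ...). Missing values are written as `.`.
#'
#' @param path CSV file path.
#' @return `read_nm_csv()` returns a validated `data.frame`;
#'   `write_nm_csv()` returns `path` invisibly.
#' @export
read_nm_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = c(".", "NA", ""))
  validate_nm_data(d)
  d
}

#' @rdname read_nm_csv
#' @param data dataset `data.frame`.
#' @export
write_nm_csv <- function(data, path) {
  validate_nm_data(data)
  out <- data
  for (j in seq_along(out)) out[[j]][is.na(out[[j]])] <- NA
  write.csv(out, path, row.names = FALSE, na = ".", quote = FALSE)
  invisible(path)
}

#' Validate a PK dataset
#'
#' Checks required columns, event coding, positive dose amounts and
#' non-decreasing `TIME` within each subject.
#'
#' @param data dataset `data.frame`.
#' @return `data` invisibly (errors name the offending column/rows).
#' @export
validate_nm_data <- function(data) {
  req <- c("ID", "TIME", "EVID", "AMT", "DV")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("dataset is missing required column(s): ", paste(miss, collapse = ", "))
  if (any(!data$EVID %in% c(0, 1)))
    stop("EVID must be 0 (observation) or 1 (dose)")
  dose <- data$EVID == 1
  if (any(is.na(data$AMT[dose])) || any(data$AMT[dose] <= 0))
    stop("dose rows (EVID=1) must have AMT > 0")
  if (any(is.na(data$TIME)) || any(data$TIME < 0))
    stop("TIME must be present and >= 0")
  bad <- unlist(lapply(split(data$TIME, data$ID),
                       function(t) any(diff(t) < 0)))
  if (any(bad))
    stop("TIME must be non-decreasing within subject; offending ID(s): ",
         paste(names(bad)[bad], collapse = ", "))
  invisible(data)
}

# Internal: flatten a dataset + spec into the vectors the compiled FOCE
# objective consumes. Covariates are taken per subject from the first row.
.flatten_nm <- function(data, spec) {
  validate_nm_data(data)
  ids <- unique(data$ID)
  n_subj <- length(ids)
  sidx <- match(data$ID, ids)

  is_obs <- data$EVID == 0 & (if ("MDV" %in% names(data))
    (is.na(data$MDV) | data$MDV == 0) else TRUE)
  obs <- data[is_obs, , drop = FALSE]
  if (any(is.na(obs$DV)))
    stop("observation rows (EVID=0, MDV=0) must have DV")
  osub <- sidx[is_obs]
  oo <- order(osub, obs$TIME)
  obs <- obs[oo, , drop = FALSE]
  osub <- osub[oo]

  dose <- data[data$EVID == 1, , drop = FALSE]
  dsub <- sidx[data$EVID == 1]
  od <- order(dsub, dose$TIME)
  dose <- dose[od, , drop = FALSE]
  dsub <- dsub[od]
  dur <- if ("RATE" %in% names(dose) && !all(is.na(dose$RATE)))
    dose$AMT / dose$RATE else rep(0.5, nrow(dose))
  if (any(!is.finite(dur)) || any(dur <= 0))
    stop("infusion durations (AMT/RATE) must be finite and > 0")

  # per-observation: ensure a dose history exists before each observation
  first_dose <- tapply(dose$TIME, dsub, min)
  fd <- rep(Inf, n_subj)
  fd[as.integer(names(first_dose))] <- first_dose
  orphan <- obs$TIME < fd[osub] | is.infinite(fd[osub])
  if (any(orphan))
    stop("observation(s) without any preceding dose for ID(s): ",
         paste(unique(ids[osub[orphan]]), collapse = ", "))

  eff <- spec$effects
  n_eff <- length(eff)
  eff_x <- matrix(0, n_subj, max(n_eff, 1))
  first_row <- data[!duplicated(data$ID), , drop = FALSE]
  first_row <- first_row[match(ids, first_row$ID), , drop = FALSE]
  if (n_eff) for (e in seq_len(n_eff)) {
    cv <- eff[[e]]$covariate
    if (!cv %in% names(data))
      stop("covariate column ", cv, " required by the model is missing")
    eff_x[, e] <- .effect_x(eff[[e]], first_row[[cv]])
  }
  form_code <- c(linear = 0L, exponential = 1L, power = 2L, categorical = 3L)
  par_code <- c(CL = 0L, V1 = 1L, Q = 2L, V2 = 3L)

  theta4 <- c(spec$theta, Q = 1, V2 = 1)[c("CL", "V1", "Q", "V2")]
  om <- spec$variance$omega
  list(ids = ids, n_subj = n_subj,
       obs_ptr = c(0L, cumsum(tabulate(osub, n_subj))),
       obs_time = as.numeric(obs$TIME), obs_dv = as.numeric(obs$DV),
       dose_ptr = c(0L, cumsum(tabulate(dsub, n_subj))),
       dose_start = as.numeric(dose$TIME), dose_amt = as.numeric(dose$AMT),
       dose_dur = as.numeric(dur),
       eff_param = if (n_eff) vapply(eff, function(e) par_code[[e$parameter]], 0L) else integer(),
       eff_form = if (n_eff) vapply(eff, function(e) form_code[[e$form]], 0L) else integer(),
       eff_x = eff_x[, seq_len(n_eff), drop = FALSE],
       eta_param = if (length(om)) unname(par_code[names(om)]) else integer(),
       theta4 = unname(theta4),
       n_obs = nrow(obs), first_row = first_row)
}
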