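#' Goodness-of-fit quantities
#'
#' Per observation: `PRED` (population prediction at `eta = 0`), `IPRED`
#' (prediction at the subject's empirical Bayes estimates), `CWRES`
#' (conditional weighted residuals: the FOCE-linearized residual
#' decorrelated by the approximate marginal covariance
#' `J Omega J' + diag(residual variance at IPRED)`), and `TAD` (time after
#' the most recent dose, with doses strictly before the observation time so
#' a pre-dose sample refers to the previous dose).
#'
#' @param data the PK dataset the model was fitted to.
#' @param fit a [fit_ppk()] result (or an `estimate = FALSE` evaluation).
#' @return A `data.frame` with columns `ID`, `TIME`, `TAD`, `DV`, `PRED`,
#'   `IPRED`, `CWRES`.
#' @export
gof_quantities <- function(data, fit) {
  stopifnot(inherits(fit, "ppk_fit"))
  spec <- fit$spec
  flat <- .flatten_nm(data, spec)
  om <- spec$variance$omega
  k <- length(om)
  out <- vector("list", flat$n_subj)
  h <- 1e-5
  for (i in seq_len(flat$n_subj)) {
    oi <- (flat$obs_ptr[i] + 1):flat$obs_ptr[i + 1]
    if (flat$obs_ptr[i + 1] == flat$obs_ptr[i]) next
    di <- (flat$dose_ptr[i] + 1):flat$dose_ptr[i + 1]
    if (flat$dose_ptr[i + 1] == flat$dose_ptr[i])
      stop("missing dose history before observations for subject ",
           flat$ids[i])
    doses <- dose_events(flat$dose_start[di], flat$dose_amt[di],
                         flat$dose_dur[di])
    typ <- unlist(model_typicals(spec, flat$first_row[i, , drop = FALSE])[1, ])
    mk_params <- function(p) {
      if (spec$n_compartments == 2)
        pk_params(p[["CL"]], p[["V1"]], p[["Q"]], p[["V2"]])
      else pk_params(p[["CL"]], p[["V1"]])
    }
    tt <- flat$obs_time[oi]
    dv <- flat$obs_dv[oi]
    pred <- pk_concentration(tt, doses, mk_params(typ))
    eta <- if (k) fit$ebes[as.character(flat$ids[i]), ] else numeric()
    pind <- typ
    if (k) pind[names(om)] <- pind[names(om)] * exp(eta)
    ipred <- pk_concentration(tt, doses, mk_params(pind))
    cwres <- rep(NA_real_, length(tt))
    if (k) {
      J <- matrix(0, length(tt), k)
      for (m in seq_len(k)) {
        e2 <- eta
        e2[m] <- e2[m] + h
        p2 <- typ
        p2[names(om)] <- p2[names(om)] * exp(e2)
        J[, m] <- (pk_concentration(tt, doses, mk_params(p2)) - ipred) / h
      }
      fv <- pmax(ipred, 1e-10)
      rvar <- spec$variance$sigma_add^2 + spec$variance$sigma_prop^2 * fv^2
      V <- J %*% diag(om^2, k) %*% t(J) + diag(rvar, length(tt))
      resid <- dv - (ipred - as.numeric(J %*% eta))
      L <- t(chol(V))
      cwres <- as.numeric(forwardsolve(L, resid))
    } else {
      fv <- pmax(pred, 1e-10)
      rvar <- spec$variance$sigma_add^2 + spec$variance$sigma_prop^2 * fv^2
      cwres <- (dv - pred) / sqrt(rvar)
    }
    tad <- vapply(tt, function(t0) {
      prior <- flat$dose_start[di][flat$dose_start[di] < t0]
      if (!length(prior))
        stop("missing dose history before an observation for subject ",
             flat$ids[i])
      t0 - max(prior)
    }, 0)
    out[[i]] <- data.frame(ID = flat$ids[i], TIME = tt, TAD = tad, DV = dv,
                           PRED = pred, IPRED = ipred, CWRES = cwres)
  }
  do.call(rbind, out)
}

#' Nonparametric bootstrap of a population-PK model
#'
#' Resamples subjects with replacement (original cohort size), refits the
#' model on each resample and summarizes every parameter by its median and
#' 2.5/97.5 percentiles. Failed refits are excluded and counted; if more
#' than 20% fail the summary is flagged unreliable.
#'
#' @param data a PK dataset.
#' @param spec the [model_spec()] to refit.
#' @param n_resamples number of bootstrap resamples (the full analysis uses
#'   1000).
#' @param seed RNG seed (resampling is bit-reproducible given the seed).
#' @param control passed to [fit_ppk()].
#' @param .resampler internal override of the ID resampler (a function of
#'   the ID vector), used for testing the identity resample.
#' @return An object of class `ppk_bootstrap`: `summary` (per-parameter
#'   median/q2.5/q97.5), `estimates` (per-resample estimates),
#'   `n_success`, `n_requested`, `unreliable`.
#' @export
ppk_bootstrap <- function(data, spec, n_resamples = 1000L, seed = NULL,
                          control = list(), .resampler = NULL) {
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(data$ID)
  blocks <- split(seq_len(nrow(data)), match(data$ID, ids))
  draws <- list()
  for (b in seq_len(n_resamples)) {
    take <- if (is.null(.resampler)) sample(length(ids), replace = TRUE)
    else match(.resampler(ids), ids)
    newd <- do.call(rbind, lapply(seq_along(take), function(j) {
      d <- data[blocks[[take[j]]], , drop = FALSE]
      d$ID <- j
      d
    }))
    f <- tryCatch(fit_ppk(newd, spec, control = control),
                  error = function(e) NULL)
    if (!is.null(f) && f$converged) {
      e <- f$estimates
      draws[[length(draws) + 1L]] <-
        setNames(e$estimate, e$name)
    }
  }
  n_success <- length(draws)
  if (!n_success) stop("all bootstrap refits failed")
  mat <- do.call(rbind, draws)
  summ <- data.frame(
    name = colnames(mat),
    median = apply(mat, 2, median),
    q2.5 = apply(mat, 2, quantile, 0.025),
    q97.5 = apply(mat, 2, quantile, 0.975),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = summ, estimates = mat, n_success = n_success,
                 n_requested = n_resamples,
                 unreliable = (n_resamples - n_success) / n_resamples > 0.2),
            class = "ppk_bootstrap")
}

#' @export
print.ppk_bootstrap <- function(x, ...) {
  cat(sprintf("<ppk_bootstrap> %d/%d successful refits%s\n", x$n_success,
              x$n_requested,
              if (x$unreliable) " [FLAGGED UNRELIABLE: >20% failures]" else ""))
  print(transform(x$summary, median = signif(median, 4),
                  q2.5 = signif(q2.5, 4), q97.5 = signif(q97.5, 4)),
        row.names = FALSE)
  invisible(x)
}

# simulate DV under a spec for the design of an existing dataset
.simulate_dv <- function(flat, spec) {
  om <- spec$variance$omega
  n_subj <- flat$n_subj
  dv <- numeric(flat$n_obs)
  typ <- model_typicals(spec, flat$first_row)
  for (i in seq_len(n_subj)) {
    oi <- (flat$obs_ptr[i] + 1):flat$obs_ptr[i + 1]
    if (flat$obs_ptr[i + 1] == flat$obs_ptr[i]) next
    di <- (flat$dose_ptr[i] + 1):flat$dose_ptr[i + 1]
    doses <- dose_events(flat$dose_start[di], flat$dose_amt[di],
                         flat$dose_dur[di])
    p <- unlist(typ[i, ])
    if (length(om)) p[names(om)] <- p[names(om)] * exp(rnorm(length(om), 0, om))
    pp <- if (spec$n_compartments == 2)
      pk_params(p[["CL"]], p[["V1"]], p[["Q"]], p[["V2"]])
    else pk_params(p[["CL"]], p[["V1"]])
    f <- pk_concentration(flat$obs_time[oi], doses, pp)
    dv[oi] <- .add_residual(f, spec$variance)
  }
  dv
}

# y = f*(1+eps_prop) + eps_add with rejection of non-positive multipliers
.add_residual <- function(f, variance) {
  n <- length(f)
  ep <- if (variance$sigma_prop > 0) {
    e <- rnorm(n, 0, variance$sigma_prop)
    bad <- which(1 + e <= 0)
    while (length(bad)) {
      e[bad] <- rnorm(length(bad), 0, variance$sigma_prop)
      bad <- bad[1 + e[bad] <= 0]
    }
    e
  } else numeric(n)
  ea <- if (variance$sigma_add > 0) rnorm(n, 0, variance$sigma_add) else numeric(n)
  f * (1 + ep) + ea
}

#' Visual predictive check
#'
#' Simulates replicate datasets under the model with the design (subjects,
#' doses, times, covariates) of the original data, computes the 5th/50th/
#' 95th percentiles of simulated concentrations per time bin, and the
#' 2.5-97.5 percentile envelope of each of those percentiles across
#' replicates; observed percentiles are reported per bin for comparison.
#' Percentiles are computed on the raw concentration scale (display is
#' conventionally on the log scale). Default bins are the distinct nominal
#' sampling times of the design.
#'
#' @param data the original PK dataset.
#' @param spec the fitted [model_spec()] (e.g. `fit$spec`).
#' @param n_replicates number of simulated replicates (the full analysis
#'   uses 1000).
#' @param seed RNG seed.
#' @param bin_edges optional numeric vector of bin edges on `TIME`; default
#'   midpoints between the distinct observed times. Empty bins are dropped
#'   with a warning.
#' @param probs percentiles of the concentration distribution, default
#'   `c(0.05, 0.5, 0.95)`.
#' @return An object of class `ppk_vpc`: a `data.frame` `bins` with the
#'   bin time, observation count, observed percentiles and the simulation
#'   envelope (`lo`/`hi`) of each percentile.
#' @export
ppk_vpc <- function(data, spec, n_replicates = 1000L, seed = NULL,
                    bin_edges = NULL, probs = c(0.05, 0.5, 0.95)) {
  if (!is.null(seed)) set.seed(seed)
  flat <- .flatten_nm(data, spec)
  tt <- flat$obs_time
  if (is.null(bin_edges)) {
    ut <- sort(unique(tt))
    bin_edges <- c(-Inf, head(ut, -1) + diff(ut) / 2, Inf)
  }
  bin <- cut(tt, bin_edges, labels = FALSE)
  bins <- sort(unique(bin))
  empty <- setdiff(seq_len(length(bin_edges) - 1), bins)
  if (length(empty))
    warning("dropping empty time bin(s): ", paste(empty, collapse = ", "))
  nb <- length(bins)
  np <- length(probs)
  obs_p <- t(vapply(bins, function(b)
    quantile(flat$obs_dv[bin == b], probs, names = FALSE), numeric(np)))
  sim_p <- array(NA_real_, c(n_replicates, nb, np))
  for (r in seq_len(n_replicates)) {
    dv <- .simulate_dv(flat, spec)
    for (bi in seq_len(nb))
      sim_p[r, bi, ] <- quantile(dv[bin == bins[bi]], probs, names = FALSE)
  }
  env_lo <- apply(sim_p, c(2, 3), quantile, 0.025)
  env_hi <- apply(sim_p, c(2, 3), quantile, 0.975)
  out <- data.frame(bin = bins,
                    time = vapply(bins, function(b) median(tt[bin == b]), 0),
                    n = vapply(bins, function(b) sum(bin == b), 0L))
  for (j in seq_len(np)) {
    pc <- paste0("p", probs[j] * 100)
    out[[paste0("obs_", pc)]] <- obs_p[, j]
    out[[paste0("sim_", pc, "_lo")]] <- env_lo[, j]
    out[[paste0("sim_", pc, "_hi")]] <- env_hi[, j]
  }
  structure(list(bins = out, n_replicates = n_replicates, probs = probs),
            class = "ppk_vpc")
}

#' @export
print.ppk_vpc <- function(x, ...) {
  cat(sprintf("<ppk_vpc> %d replicates, %d bins\n", x$n_replicates,
              nrow(x$bins)))
  print(transform(x$bins), row.names = FALSE)
  invisible(x)
}
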