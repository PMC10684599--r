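#' Univariable MR for a single exposure
#'
#' One exposure at a time, instrumented by its own polygenic score only —
#' the comparator that does not account for the correlation with the other
#' two exposures.  Continuous phenotypes use 2SLS (which here reduces to
#' the Wald ratio, covariate-adjusted); binary phenotypes use the plug-in
#' probit second stage with bootstrap standard errors.  When exposures
#' share instruments, the univariable estimand is a correlation-weighted
#' sum of all three causal effects, which is exactly the homogenization
#' bias this package exists to expose.
#'
#' @inheritParams fit_mvmr_probit
#' @param exposure Exposure name or index.
#' @return A `causal_estimate` with method `"UVMR"`.
#' @export
fit_uvmr <- function(cohort, instruments, exposure, phenotype,
                     covariates = cohort$covariates, normalize = TRUE,
                     f_gate = 10, n_boot = 200, boot_seed = 1L,
                     min_cases = 200, or_factor = 1.6,
                     individuals = NULL) {
  stopifnot(inherits(instruments, "instrument_set"))
  j <- if (is.character(exposure)) match(exposure, bcaa_names())
       else as.integer(exposure)
  if (is.na(j) || j < 1L || j > 3L) stop("unknown exposure: ", exposure)
  phen <- .resolve_phenotype(cohort, phenotype)
  idx <- individuals %||% seq_along(phen$values)
  idx <- idx[!is.na(phen$values[idx])]
  y <- phen$values[idx]
  X <- cohort$exposures[idx, j, drop = FALSE]
  if (normalize) X[, 1] <- inverse_normal_transform(X[, 1])
  S <- instruments$scores[idx, j, drop = FALSE]
  C <- .design(if (is.null(covariates)) NULL
               else as.matrix(covariates)[idx, , drop = FALSE],
               length(idx))
  fs <- .first_stage(X, S, C, bcaa_names()[j])
  if (fs$f_individual < f_gate) {
    warning("univariable first-stage F below ", f_gate, " for ",
            bcaa_names()[j], call. = FALSE)
  }
  if (phen$kind == "binary") {
    if (!all(y %in% c(0, 1))) stop("probit outcome must be coded 0/1")
    n_cases <- sum(y == 1)
    if (n_cases < min_cases) {
      stop("phenotype ", phen$name, " has ", n_cases,
           " cases; fewer than ", min_cases, " cases are excluded")
    }
    fit <- .probit(cbind(fs$C, fs$fitted), y)
    pick <- ncol(fs$C) + 1L
    beta <- fit$coef[pick]
    se <- if (n_boot > 0) {
      withr::with_seed(boot_seed, .probit_boot(y, fs, pick, n_boot))
    } else fit$se[pick]
    .causal_rows(fs$exposures, phen, "UVMR", "probit", beta, se,
                 length(idx), f_stat = unname(fs$f_individual),
                 sw_f = unname(fs$sw_f), or_factor = or_factor)
  } else {
    est <- .tsls(y, fs)
    .causal_rows(fs$exposures, phen, "UVMR", "linear", est$beta, est$se,
                 length(idx), f_stat = unname(fs$f_individual),
                 sw_f = unname(fs$sw_f))
  }
}

#' Observational regression of a phenotype on one measured exposure
#'
#' The conventional epidemiological comparator: linear (continuous) or
#' probit (binary) regression of the phenotype on a single measured
#' exposure plus covariates.  Subject to confounding by the latent
#' confounder and to mutual confounding by the other correlated exposures.
#'
#' @inheritParams fit_uvmr
#' @return A `causal_estimate` with method `"OBS"`.
#' @export
fit_observational <- function(cohort, exposure, phenotype,
                              covariates = cohort$covariates,
                              normalize = TRUE, min_cases = 200,
                              or_factor = 1.6, individuals = NULL) {
  j <- if (is.character(exposure)) match(exposure, bcaa_names())
       else as.integer(exposure)
  if (is.na(j) || j < 1L || j > 3L) stop("unknown exposure: ", exposure)
  phen <- .resolve_phenotype(cohort, phenotype)
  idx <- individuals %||% seq_along(phen$values)
  idx <- idx[!is.na(phen$values[idx])]
  y <- phen$values[idx]
  x <- cohort$exposures[idx, j]
  if (normalize) x <- inverse_normal_transform(x)
  C <- .design(if (is.null(covariates)) NULL
               else as.matrix(covariates)[idx, , drop = FALSE],
               length(idx))
  design <- cbind(C, exposure = x)
  pick <- ncol(design)
  if (phen$kind == "binary") {
    if (!all(y %in% c(0, 1))) stop("probit outcome must be coded 0/1")
    n_cases <- sum(y == 1)
    if (n_cases < min_cases) {
      stop("phenotype ", phen$name, " has ", n_cases,
           " cases; fewer than ", min_cases, " cases are excluded")
    }
    fit <- .probit(design, y)
    .causal_rows(bcaa_names()[j], phen, "OBS", "probit",
                 fit$coef[pick], fit$se[pick], length(idx),
                 or_factor = or_factor)
  } else {
    fit <- .ols(design, y)
    df <- length(y) - fit$rank
    vc <- sum(fit$resid^2) / df * chol2inv(qr.R(fit$qr))
    .causal_rows(bcaa_names()[j], phen, "OBS", "linear",
                 fit$coef[pick], sqrt(diag(vc))[pick], length(idx))
  }
}

#' Fit all three methods for one phenotype on an identical sample
#'
#' Computes MVMR (three exposures jointly), UVMR (each exposure with its
#' own score) and the observational regression for one phenotype, forcing
#' all nine estimates onto the same complete-case analysis sample so that
#' cross-method contrasts are never a sample artifact.
#'
#' @inheritParams fit_mvmr_probit
#' @return A 9-row `causal_estimate` table.
#' @export
fit_all_methods <- function(cohort, instruments, phenotype,
                            covariates = cohort$covariates,
                            normalize = TRUE, n_boot = 200, boot_seed = 1L,
                            min_cases = 200, individuals = NULL) {
  phen <- .resolve_phenotype(cohort, phenotype)
  idx <- individuals %||% seq_along(phen$values)
  idx <- idx[!is.na(phen$values[idx])]
  common <- list(covariates = covariates, normalize = normalize,
                 individuals = idx)
  mv <- if (phen$kind == "binary") {
    fit_mvmr_probit(cohort, instruments, phenotype,
                    covariates = covariates, normalize = normalize,
                    n_boot = n_boot, boot_seed = boot_seed,
                    min_cases = min_cases, individuals = idx)
  } else {
    fit_mvmr_linear(cohort, instruments, phenotype,
                    covariates = covariates, normalize = normalize,
                    individuals = idx)
  }
  uv <- lapply(1:3, function(j) {
    fit_uvmr(cohort, instruments, j, phenotype, covariates = covariates,
             normalize = normalize, n_boot = n_boot,
             boot_seed = boot_seed + j, min_cases = min_cases,
             individuals = idx)
  })
  ob <- lapply(1:3, function(j) {
    fit_observational(cohort, j, phenotype, covariates = covariates,
                      normalize = normalize, min_cases = min_cases,
                      individuals = idx)
  })
  out <- data.table::rbindlist(c(list(mv), uv, ob), fill = TRUE)
  out <- as.data.frame(out)
  class(out) <- c("causal_estimate", "data.frame")
  attr(out, "first_stage") <- attr(mv, "first_stage")
  out
}
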