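#' First-stage regressions of exposures on polygenic-score instruments
#'
#' Regresses each (inverse rank-normalized) exposure on all three scores
#' plus covariates — every exposure's first stage uses the full instrument
#' set, since the scores share variants — and computes two instrument
#' strength diagnostics per exposure: the individual F statistic (joint
#' null that all three score coefficients are zero) and the
#' Sanderson-Windmeijer conditional F ([conditional_f()]), which asks
#' whether the scores still predict the exposure once the other exposures'
#' fitted values are held fixed.
#'
#' @param cohort A `bcaa_cohort`.
#' @param instruments An `instrument_set`.
#' @param covariates Covariates; defaults to the cohort covariates.
#' @param normalize Inverse rank-normalize exposures (default TRUE); set
#'   FALSE to fit on the raw standardized scale.
#' @param exposures Indices of exposures to model (default all three).
#' @param individuals Optional row subset (e.g. a phenotype's complete
#'   cases).
#' @return Object of class `first_stage_fit`: coefficient matrix, fitted
#'   values, residuals, `f_individual`, `sw_f`, and the design pieces
#'   needed by the second stage.
#' @export
fit_first_stage <- function(cohort, instruments,
                            covariates = cohort$covariates,
                            normalize = TRUE, exposures = 1:3,
                            individuals = NULL) {
  stopifnot(inherits(cohort, "bcaa_cohort"),
            inherits(instruments, "instrument_set"))
  idx <- individuals %||% seq_len(nrow(cohort$exposures))
  X <- cohort$exposures[idx, exposures, drop = FALSE]
  if (normalize) X <- apply(X, 2, inverse_normal_transform)
  S <- instruments$scores[idx, , drop = FALSE]
  C <- .design(if (is.null(covariates)) NULL
               else as.matrix(covariates)[idx, , drop = FALSE],
               length(idx))
  .first_stage(X, S, C, bcaa_names()[exposures])
}

.first_stage <- function(X, S, C, exposure_names) {
  n <- nrow(X)
  Z <- cbind(C, S)
  fit1 <- .ols(Z, X)
  fit0 <- .ols(C, X, allow_deficient = TRUE)
  kS <- ncol(S)
  df <- n - fit1$rank
  f_ind <- ((fit0$rss - fit1$rss) / kS) / (fit1$rss / df)
  fs <- structure(list(coef = fit1$coef, fitted = fit1$fitted,
                       resid = fit1$resid, X = X, S = S, C = C, n = n,
                       exposures = exposure_names,
                       f_individual = stats::setNames(f_ind, exposure_names)),
                  class = "first_stage_fit")
  fs$sw_f <- stats::setNames(
    vapply(seq_along(exposure_names), function(j) conditional_f(fs, j), 0),
    exposure_names)
  fs
}

#' Sanderson-Windmeijer conditional F statistic
#'
#' The exposure is regressed on the other exposures' first-stage fitted
#' values plus covariates; the residual is then regressed on the
#' instruments, and the resulting joint test is rescaled to its conditional
#' numerator degrees of freedom, the number of instruments minus the
#' number of other exposures.  When only one exposure is modeled the
#' statistic reduces exactly to the individual first-stage F.  A weak
#' conditional instrument — an exposure whose genetic value is a linear
#' combination of the others' — drives this statistic toward its null
#' level even when the individual F is enormous.
#'
#' @param first_stage A `first_stage_fit`.
#' @param exposure Index of the exposure within the fit.
#' @return The conditional F statistic (scalar).
#' @export
conditional_f <- function(first_stage, exposure) {
  stopifnot(inherits(first_stage, "first_stage_fit"))
  X <- first_stage$X
  C <- first_stage$C
  S <- first_stage$S
  n <- first_stage$n
  others <- setdiff(seq_len(ncol(X)), exposure)
  df1 <- ncol(S) - length(others)
  if (df1 <= 0) {
    stop("conditional F undefined: fewer instruments than other exposures")
  }
  if (length(others)) {
    base <- cbind(C, first_stage$fitted[, others, drop = FALSE])
    qrb <- qr(base)
    if (qrb$rank < ncol(base)) {
      stop("other exposures' fitted values are collinear with the ",
           "covariates; conditional F undefined")
    }
    r <- qr.resid(qrb, X[, exposure])
  } else {
    r <- X[, exposure]
  }
  rss0 <- .ols(C, r, allow_deficient = TRUE)$rss
  fit1 <- .ols(cbind(C, S), r, allow_deficient = TRUE)
  den_df <- n - fit1$rank - length(others)
  ((rss0 - fit1$rss) / df1) / (fit1$rss / den_df)
}

# Shared plumbing: resolve a phenotype argument to (values, name, category,
# kind) against the cohort tables.
.resolve_phenotype <- function(cohort, phenotype) {
  if (is.character(phenotype) && length(phenotype) == 1L) {
    if (!phenotype %in% names(cohort$phenotypes)) {
      stop("unknown phenotype: ", phenotype)
    }
    info <- cohort$phenotype_info
    i <- match(phenotype, info$name)
    list(values = cohort$phenotypes[[phenotype]], name = phenotype,
         category = info$category[i], kind = info$kind[i])
  } else {
    v <- as.numeric(phenotype)
    kind <- if (all(v %in% c(0, 1, NA))) "binary" else "continuous"
    list(values = v, name = "phenotype", category = NA_character_,
         kind = kind)
  }
}

.causal_rows <- function(exposures, phen, method, scale, beta, se, n_used,
                         f_stat = NA_real_, sw_f = NA_real_,
                         or_factor = NA_real_) {
  z <- beta / se
  ci <- qnorm(0.975)
  out <- data.frame(
    phenotype = phen$name, category = phen$category,
    exposure = exposures, method = method, scale = scale,
    beta = beta, se = se,
    ci_low = beta - ci * se, ci_high = beta + ci * se,
    p = 2 * pnorm(-abs(z)), n_used = n_used,
    f_statistic = f_stat, sw_f = sw_f,
    stringsAsFactors = FALSE
  )
  if (scale == "probit" && is.finite(or_factor)) {
    out$odds_ratio <- exp(or_factor * beta)
    out$or_ci_low <- exp(or_factor * out$ci_low)
    out$or_ci_high <- exp(or_factor * out$ci_high)
  }
  rownames(out) <- NULL
  class(out) <- c("causal_estimate", "data.frame")
  out
}

#' Multivariable MR by two-stage least squares (continuous outcome)
#'
#' First stage: each exposure on the three scores plus covariates.  Second
#' stage: the phenotype on the three fitted exposures plus covariates.
#' Standard errors use the usual 2SLS correction — second-stage residuals
#' are recomputed with the observed, not fitted, exposures.  With three
#' scores instrumenting three exposures the system is just identified, and
#' the estimate equals the closed-form instrumental-variables solution.
#'
#' Each total causal effect is the effect of raising one exposure by 1 SD
#' while holding the other two fixed.
#'
#' @param cohort A `bcaa_cohort`.
#' @param instruments An `instrument_set`.
#' @param phenotype Phenotype name (looked up in the cohort) or a numeric
#'   vector.
#' @param covariates Covariates; defaults to the cohort covariates.
#' @param normalize Inverse rank-normalize exposures (default TRUE).
#' @param f_gate First-stage F below which a warning is issued (default
#'   10); gate failures are logged, not fatal.
#' @param individuals Optional row subset; missing phenotype values are
#'   always dropped (complete-case per phenotype).
#' @return A `causal_estimate` data frame with one row per exposure
#'   (method `"MVMR"`, scale `"linear"`), with the first-stage fit attached
#'   as attribute `first_stage`.
#' @export
fit_mvmr_linear <- function(cohort, instruments, phenotype,
                            covariates = cohort$covariates,
                            normalize = TRUE, f_gate = 10,
                            individuals = NULL) {
  phen <- .resolve_phenotype(cohort, phenotype)
  idx <- individuals %||% seq_along(phen$values)
  idx <- idx[!is.na(phen$values[idx])]
  y <- phen$values[idx]
  fs <- fit_first_stage(cohort, instruments, covariates = covariates,
                        normalize = normalize, individuals = idx)
  k <- ncol(fs$C) + 3L
  if (length(idx) <= k) {
    stop("only ", length(idx), " complete cases for ", phen$name,
         "; need more than ", k, " parameters")
  }
  if (any(fs$f_individual < f_gate) || any(fs$sw_f < f_gate)) {
    warning("first-stage F below ", f_gate, " for ", phen$name,
            "; instruments may be weak", call. = FALSE)
  }
  est <- .tsls(y, fs)
  out <- .causal_rows(fs$exposures, phen, "MVMR", "linear",
                      est$beta, est$se, length(idx),
                      f_stat = unname(fs$f_individual),
                      sw_f = unname(fs$sw_f))
  attr(out, "first_stage") <- fs
  out
}

# 2SLS point estimates and corrected SEs given a first-stage fit.
.tsls <- function(y, fs) {
  Xhat <- cbind(fs$C, fs$fitted)
  Xobs <- cbind(fs$C, fs$X)
  xtx <- crossprod(Xhat)
  bhat <- solve(xtx, crossprod(Xhat, y))
  u <- y - Xobs %*% bhat
  k <- ncol(Xhat)
  s2 <- sum(u^2) / (fs$n - k)
  vc <- s2 * solve(xtx)
  pick <- ncol(fs$C) + seq_len(ncol(fs$X))
  list(beta = as.vector(bhat)[pick], se = sqrt(diag(vc))[pick],
       coef = as.vector(bhat), vcov = vc)
}

#' Multivariable MR with a probit second stage (binary outcome)
#'
#' Plug-in two-stage estimator: the binary phenotype is regressed by
#' probit maximum likelihood on the three first-stage fitted exposures
#' plus covariates.  Standard errors come from a nonparametric bootstrap
#' over individuals in which both stages are refit (plug-in analytic SEs
#' understate uncertainty because they ignore first-stage noise).
#' Estimates are reported on the probit scale together with approximate
#' odds ratios via [probit_to_or()].
#'
#' @inheritParams fit_mvmr_linear
#' @param n_boot Bootstrap replicates (default 200).  `n_boot = 0` falls
#'   back to the plug-in analytic SEs.
#' @param boot_seed Seed for the bootstrap resampling.
#' @param min_cases Minimum case count (default 200).
#' @param or_factor Probit-to-logit scale factor for the odds-ratio
#'   approximation (default 1.6).
#' @return A `causal_estimate` with scale `"probit"` and odds-ratio
#'   columns.
#' @export
fit_mvmr_probit <- function(cohort, instruments, phenotype,
                            covariates = cohort$covariates,
                            normalize = TRUE, f_gate = 10,
                            n_boot = 200, boot_seed = 1L,
                            min_cases = 200, or_factor = 1.6,
                            individuals = NULL) {
  phen <- .resolve_phenotype(cohort, phenotype)
  idx <- individuals %||% seq_along(phen$values)
  idx <- idx[!is.na(phen$values[idx])]
  y <- phen$values[idx]
  if (!all(y %in% c(0, 1))) stop("probit outcome must be coded 0/1")
  n_cases <- sum(y == 1)
  if (n_cases < min_cases) {
    stop("phenotype ", phen$name, " has ", n_cases, " cases; fewer than ",
         min_cases, " cases are excluded")
  }
  fs <- fit_first_stage(cohort, instruments, covariates = covariates,
                        normalize = normalize, individuals = idx)
  if (any(fs$f_individual < f_gate) || any(fs$sw_f < f_gate)) {
    warning("first-stage F below ", f_gate, " for ", phen$name,
            "; instruments may be weak", call. = FALSE)
  }
  fit <- .probit(cbind(fs$C, fs$fitted), y)
  pick <- ncol(fs$C) + seq_len(ncol(fs$X))
  beta <- fit$coef[pick]
  if (n_boot > 0) {
    se <- withr::with_seed(boot_seed,
                           .probit_boot(y, fs, pick, n_boot))
  } else {
    se <- fit$se[pick]
  }
  out <- .causal_rows(fs$exposures, phen, "MVMR", "probit", beta, se,
                      length(idx), f_stat = unname(fs$f_individual),
                      sw_f = unname(fs$sw_f), or_factor = or_factor)
  attr(out, "first_stage") <- fs
  out
}

# Probit ML via glm.fit; reports convergence and separation.
.probit <- function(design, y, start = NULL) {
  fit <- suppressWarnings(
    glm.fit(design, y, family = binomial(link = "probit"), start = start)
  )
  if (!fit$converged) {
    stop("probit regression did not converge after ", fit$iter,
         " iterations; deviance ", signif(fit$deviance, 6))
  }
  if (any(abs(fit$coefficients) > 15) ||
      all(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)) {
    warning("probit fit shows signs of perfect separation", call. = FALSE)
  }
  R <- qr.R(fit$qr)
  vc <- chol2inv(R)
  list(coef = fit$coefficients, se = sqrt(diag(vc)), fit = fit)
}

.probit_boot <- function(y, fs, pick, n_boot) {
  n <- fs$n
  Z <- cbind(fs$C, fs$S)
  full <- .probit(cbind(fs$C, fs$fitted), y)
  coefs <- matrix(NA_real_, n_boot, length(pick))
  for (b in seq_len(n_boot)) {
    ii <- sample.int(n, n, replace = TRUE)
    xh <- qr.fitted(qr(Z[ii, , drop = FALSE]), fs$X[ii, , drop = FALSE])
    fb <- tryCatch(
      .probit(cbind(fs$C[ii, , drop = FALSE], xh), y[ii],
              start = full$coef),
      error = function(e) NULL)
    if (!is.null(fb)) coefs[b, ] <- fb$coef[pick]
  }
  apply(coefs, 2, sd, na.rm = TRUE)
}

#' Convert a probit coefficient to an approximate odds ratio
#'
#' Uses the standard logit-to-probit scaling, `OR = exp(factor * beta)`
#' with `factor = 1.6` by default.
#'
#' @param beta_probit Probit-scale coefficient(s).
#' @param factor Scale factor (default 1.6).
#' @return Odds ratio(s).
#' @export
#' @examples
#' probit_to_or(0.5)  # exp(0.8)
probit_to_or <- function(beta_probit, factor = 1.6) {
  exp(factor * beta_probit)
}

#' Fit MVMR for one phenotype, dispatching on its kind
#'
#' Calls [fit_mvmr_linear()] for continuous phenotypes and
#' [fit_mvmr_probit()] for binary ones.
#'
#' @inheritParams fit_mvmr_probit
#' @param ... Passed to the kind-specific fitter.
#' @return A `causal_estimate`.
#' @export
fit_mvmr <- function(cohort, instruments, phenotype, ...) {
  phen <- .resolve_phenotype(cohort, phenotype)
  if (phen$kind == "binary") {
    fit_mvmr_probit(cohort, instruments, phenotype, ...)
  } else {
    fit_mvmr_linear(cohort, instruments, phenotype, ...)
  }
}

#' @export
print.causal_estimate <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 4)
  print(df)
  invisible(x)
}
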