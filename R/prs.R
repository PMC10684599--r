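#' Build cross-fitted polygenic-score instruments
#'
#' For each exposure, a genome-wide association scan is rerun within each
#' training fold, and held-out individuals are scored with the
#' training-fold marginal betas of variants passing the inclusion p-value
#' (variants failing quality control are never scored).  Cross-fitting
#' guarantees that no individual's score uses weights estimated from their
#' own data, removing overfitting leakage, which would otherwise reintroduce
#' the confounded exposure noise into the instrument.  Scores are
#' standardized to mean 0, variance 1 over the full sample, so downstream
#' effects are interpreted per 1 SD of the score.
#'
#' @param cohort A `bcaa_cohort`.
#' @param k_folds Number of cross-fitting folds (>= 2, default 5).
#' @param p_inclusion Training-fold marginal p-value below which a variant
#'   enters the score (default 0.05).
#' @param covariates Covariates for the fold scans; defaults to the cohort
#'   covariates.
#' @param seed Seed for the fold assignment (default: cohort seed + 1000).
#' @return An object of class `instrument_set`: list with `scores` (n x 3
#'   standardized matrix), `folds` (fold label per individual), `weights`
#'   (per fold, per exposure named weight vectors) and `diagnostics` (per
#'   exposure partial R-squared and first-stage F; see
#'   [instrument_relevance()]).
#' @export
build_instruments <- function(cohort, k_folds = 5, p_inclusion = 0.05,
                              covariates = cohort$covariates,
                              seed = NULL) {
  stopifnot(inherits(cohort, "bcaa_cohort"), k_folds >= 2)
  .assert_prob(p_inclusion, "p_inclusion")
  n <- nrow(cohort$dosages)
  seed <- seed %||% (cohort$truth$config$seed + 1000L)
  folds <- withr::with_seed(seed,
    sample(rep_len(seq_len(k_folds), n)))
  scores <- matrix(NA_real_, n, 3, dimnames = list(NULL, bcaa_names()))
  weights <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    train <- which(folds != f)
    test <- which(folds == f)
    wf <- vector("list", 3)
    names(wf) <- bcaa_names()
    for (j in 1:3) {
      g <- scan_exposure(cohort, j, covariates = covariates,
                         individuals = train)
      keep <- !g$excluded & !g$monomorphic & !is.na(g$p_raw) &
        g$p_raw < p_inclusion
      if (!any(keep)) {
        stop("fold ", f, ", exposure ", bcaa_names()[j],
             ": no variants passed p < ", p_inclusion,
             "; increase effect sizes or p_inclusion")
      }
      w <- stats::setNames(g$beta[keep], g$variant[keep])
      wf[[j]] <- w
      scores[test, j] <-
        cohort$dosages[test, names(w), drop = FALSE] %*% w
    }
    weights[[f]] <- wf
  }
  scores <- scale(scores)
  attr(scores, "scaled:center") <- NULL
  attr(scores, "scaled:scale") <- NULL
  inst <- instrument_set(scores, folds, weights)
  inst$diagnostics <- instrument_relevance(inst, cohort,
                                           covariates = covariates)
  inst
}

#' Construct an instrument set from a score matrix
#'
#' Low-level constructor used by [build_instruments()] and by tests that
#' need hand-built scores.
#'
#' @param scores n x 3 numeric matrix of per-exposure scores.
#' @param folds Optional fold assignment vector.
#' @param weights Optional per-fold weight lists.
#' @return An `instrument_set`.
#' @export
instrument_set <- function(scores, folds = NULL, weights = NULL) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 3L, is.numeric(scores))
  colnames(scores) <- bcaa_names()
  structure(list(scores = scores, folds = folds, weights = weights,
                 diagnostics = NULL),
            class = "instrument_set")
}

#' Instrument relevance diagnostics
#'
#' For each exposure: the partial R-squared of the three scores jointly,
#' given the covariates, and the first-stage F statistic of the joint null
#' that all three score coefficients are zero.
#'
#' @param instruments An `instrument_set`.
#' @param cohort A `bcaa_cohort`.
#' @param covariates Covariates; defaults to the cohort covariates.
#' @param normalize Inverse rank-normalize the exposures (default TRUE),
#'   matching the first-stage convention.
#' @return Data frame with columns `exposure`, `partial_r2`, `f_statistic`.
#' @export
instrument_relevance <- function(instruments, cohort,
                                 covariates = cohort$covariates,
                                 normalize = TRUE) {
  stopifnot(inherits(instruments, "instrument_set"))
  n <- nrow(instruments$scores)
  C <- .design(covariates, n)
  S <- instruments$scores
  out <- lapply(1:3, function(j) {
    y <- cohort$exposures[, j]
    if (normalize) y <- inverse_normal_transform(y)
    fit0 <- .ols(C, y)
    fit1 <- .ols(cbind(C, S), y)
    df1 <- n - fit1$rank
    f <- ((fit0$rss - fit1$rss) / 3) / (fit1$rss / df1)
    data.frame(exposure = bcaa_names()[j],
               partial_r2 = 1 - fit1$rss / fit0$rss,
               f_statistic = f, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("<instrument_set> n = ", nrow(x$scores),
      if (!is.null(x$folds)) paste0(", folds = ", max(x$folds)), "\n",
      sep = "")
  if (!is.null(x$diagnostics)) {
    print(transform(x$diagnostics,
                    partial_r2 = round(partial_r2, 3),
                    f_statistic = round(f_statistic, 1)))
  }
  invisible(x)
}
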