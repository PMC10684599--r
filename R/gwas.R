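#' Effective sample size of an imputed variant
#'
#' `2 * maf * (1 - maf) * n * q`, a dosage-information measure used as a
#' quality-control filter: variants with imputation quality below 0.4 or
#' effective sample size below 30 are excluded from association testing.
#'
#' @param maf Minor allele frequency, in `[0, 0.5]` (fold to the minor
#'   allele first; values above 0.5 are an error).
#' @param q Imputation quality in `[0, 1]`.
#' @param n Study size.
#' @return Numeric vector of effective sample sizes.
#' @export
#' @examples
#' effective_n(0.5, 1, 100)  # 50
effective_n <- function(maf, q, n) {
  if (any(maf > 0.5, na.rm = TRUE)) {
    stop("maf > 0.5: fold to the minor allele before computing effective_n")
  }
  .assert_prob(maf[!is.na(maf)], "maf", lo = 0, hi = 0.5, open = FALSE)
  .assert_prob(q[!is.na(q)], "q", open = FALSE)
  stopifnot(all(n > 0))
  2 * maf * (1 - maf) * n * q
}

# QC exclusion rule shared by the scan and the instrument builder.
.qc_excluded <- function(maf, q, n, min_eff_n = 30, min_q = 0.4) {
  q < min_q | effective_n(maf, q, n) < min_eff_n
}

#' Genomic control adjustment
#'
#' Estimates the inflation factor as the median observed chi-square over
#' the median of the 1-df chi-square reference (0.4549), and divides the
#' test statistics by it when it exceeds 1.  Deflation is never applied
#' (lambda is floored at 1).
#'
#' @param chi2 Vector of 1-df chi-square statistics (NAs ignored).
#' @return List with `lambda` (estimated), `lambda_applied`
#'   (`max(1, lambda)`) and `p_gc` (adjusted p-values, same length as
#'   `chi2`).
#' @export
genomic_control <- function(chi2) {
  if (!sum(!is.na(chi2))) stop("genomic_control needs at least one test")
  lambda <- median(chi2, na.rm = TRUE) / qchisq(0.5, 1)
  lambda_applied <- max(1, lambda)
  list(lambda = lambda, lambda_applied = lambda_applied,
       p_gc = pchisq(chi2 / lambda_applied, 1, lower.tail = FALSE))
}

#' Per-variant association scan for one exposure
#'
#' Ordinary least squares of the (inverse rank-normalized) exposure on each
#' variant's dosage plus covariates, computed by residualizing both on the
#' covariate design (Frisch-Waugh), which reproduces the joint fit exactly.
#' Quality-control flags (imputation quality < 0.4 or effective sample
#' size < 30) are applied before significance calls; significance requires
#' the genomic-control-adjusted p-value to fall below `gw_threshold`.
#'
#' @param cohort A `bcaa_cohort`.
#' @param exposure Exposure name or index (1 = leucine, 2 = isoleucine,
#'   3 = valine).
#' @param covariates Data frame / matrix of covariates; defaults to the
#'   cohort covariates.
#' @param normalize Apply the inverse rank-normal transform to the exposure
#'   first (default TRUE).
#' @param gw_threshold Genome-wide significance threshold on the adjusted
#'   p-value (default 1.7e-9).
#' @param individuals Optional row subset (indices) to scan, e.g. a
#'   training fold.
#' @return A data.frame of class `gwas_result` with one row per variant:
#'   `variant`, `beta`, `se`, `chi2`, `p_raw`, `p_gc`, `maf` (folded,
#'   estimated from the scanned dosages), `q`, `eff_n`, `monomorphic`,
#'   `excluded`, `significant`.  The genomic-control lambda is attached as
#'   attribute `lambda`.
#' @export
scan_exposure <- function(cohort, exposure, covariates = cohort$covariates,
                          normalize = TRUE, gw_threshold = 1.7e-9,
                          individuals = NULL) {
  stopifnot(inherits(cohort, "bcaa_cohort"))
  j <- if (is.character(exposure)) match(exposure, bcaa_names())
       else as.integer(exposure)
  if (is.na(j) || j < 1L || j > 3L) stop("unknown exposure: ", exposure)
  idx <- individuals %||% seq_len(nrow(cohort$dosages))
  y <- cohort$exposures[idx, j]
  if (normalize) y <- inverse_normal_transform(y)
  D <- cohort$dosages[idx, , drop = FALSE]
  C <- .design(if (is.null(covariates)) NULL
               else as.matrix(covariates)[idx, , drop = FALSE], length(idx))
  n <- length(idx)

  qrc <- qr(C)
  yr <- qr.resid(qrc, y)
  Dr <- qr.resid(qrc, D)
  sxx <- colSums(Dr * Dr)
  mono <- sxx < 1e-10
  sxy <- as.vector(crossprod(Dr, yr))
  beta <- ifelse(mono, NA_real_, sxy / sxx)
  syy <- sum(yr^2)
  df <- n - qrc$rank - 1L
  rss <- pmax(syy - beta^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  chi2 <- (beta / se)^2
  p_raw <- pchisq(chi2, 1, lower.tail = FALSE)

  freq <- colMeans(D) / 2
  maf <- pmin(freq, 1 - freq)
  q <- cohort$variant_info$q
  effn <- effective_n(maf, q, n)
  excluded <- .qc_excluded(maf, q, n)

  gc <- genomic_control(chi2[!excluded & !mono])
  p_gc <- pchisq(chi2 / gc$lambda_applied, 1, lower.tail = FALSE)

  out <- data.frame(variant = colnames(D), beta = beta, se = se,
                    chi2 = chi2, p_raw = p_raw, p_gc = p_gc,
                    maf = maf, q = q, eff_n = effn,
                    monomorphic = mono, excluded = excluded,
                    significant = !excluded & !mono &
                      !is.na(p_gc) & p_gc < gw_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "lambda") <- gc$lambda
  attr(out, "lambda_applied") <- gc$lambda_applied
  attr(out, "gw_threshold") <- gw_threshold
  attr(out, "exposure") <- bcaa_names()[j]
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Stepwise conditional selection of independent association signals
#'
#' Greedy forward selection on individual-level data: repeatedly add the
#' candidate variant with the smallest conditional p-value (from the
#' regression of the exposure on the already-selected variants, the
#' candidate, and covariates) while that p-value is below the threshold.
#' Candidates whose dosage is explained with r-squared above `r2_cap` by
#' the selected set (plus covariates) are skipped as collinear.  Ties break
#' deterministically by (p-value, variant id).
#'
#' @param cohort A `bcaa_cohort`.
#' @param exposure Exposure name or index.
#' @param candidates Character vector of candidate variant ids (typically
#'   the genome-wide-significant variants).
#' @param covariates Covariates; defaults to the cohort covariates.
#' @param p_threshold Conditional selection threshold (defaults to the
#'   genome-wide threshold 1.7e-9).
#' @param r2_cap Collinearity cap (default 0.9).
#' @param normalize Inverse rank-normalize the exposure (default TRUE).
#' @return List with `selected` (variant ids in selection order),
#'   `conditional_p` (drop-one conditional p-values of the selected set in
#'   the joint model) and `skipped_collinear`.
#' @export
stepwise_conditional <- function(cohort, exposure, candidates,
                                 covariates = cohort$covariates,
                                 p_threshold = 1.7e-9, r2_cap = 0.9,
                                 normalize = TRUE) {
  stopifnot(inherits(cohort, "bcaa_cohort"), length(candidates) > 0)
  miss <- setdiff(candidates, colnames(cohort$dosages))
  if (length(miss)) stop("unknown candidate variants: ",
                         paste(miss, collapse = ", "))
  j <- if (is.character(exposure)) match(exposure, bcaa_names())
       else as.integer(exposure)
  y <- cohort$exposures[, j]
  if (normalize) y <- inverse_normal_transform(y)
  n <- length(y)
  C <- .design(covariates, n)
  D <- cohort$dosages[, candidates, drop = FALSE]
  storage.mode(D) <- "double"
  d_var <- apply(D, 2, var) * (n - 1)

  selected <- character(0)
  skipped <- character(0)
  remaining <- candidates
  repeat {
    base <- cbind(C, D[, selected, drop = FALSE])
    qrb <- qr(base)
    yr <- qr.resid(qrb, y)
    cand <- setdiff(remaining, c(selected, skipped))
    if (!length(cand)) break
    Dr <- qr.resid(qrb, D[, cand, drop = FALSE])
    sxx <- colSums(Dr * Dr)
    coll <- sxx / d_var[cand] < (1 - r2_cap)
    if (any(coll)) {
      skipped <- c(skipped, cand[coll])
      cand <- cand[!coll]
      if (!length(cand)) break
      Dr <- Dr[, cand, drop = FALSE]
      sxx <- sxx[cand]
    }
    beta <- as.vector(crossprod(Dr, yr)) / sxx
    df <- n - qrb$rank - 1L
    rss <- pmax(sum(yr^2) - beta^2 * sxx, 0)
    chi2 <- beta^2 * sxx / (rss / df)
    p <- pchisq(chi2, 1, lower.tail = FALSE)
    ord <- order(p, cand)
    if (!is.finite(p[ord[1]]) || p[ord[1]] >= p_threshold) break
    selected <- c(selected, cand[ord[1]])
  }

  cond_p <- numeric(0)
  if (length(selected)) {
    full <- cbind(C, D[, selected, drop = FALSE])
    fit <- .ols(full, y, allow_deficient = TRUE)
    df <- n - fit$rank
    sigma2 <- fit$rss / df
    cond_p <- vapply(selected, function(v) {
      red <- cbind(C, D[, setdiff(selected, v), drop = FALSE])
      rss0 <- .ols(red, y, allow_deficient = TRUE)$rss
      f <- (rss0 - fit$rss) / sigma2
      pchisq(f, 1, lower.tail = FALSE)
    }, 0)
  }
  list(selected = selected, conditional_p = cond_p,
       skipped_collinear = skipped)
}

#' @export
print.gwas_result <- function(x, ...) {
  cat("<gwas_result> exposure: ", attr(x, "exposure") %||% "?",
      ", variants: ", nrow(x),
      ", lambda: ", round(attr(x, "lambda"), 3),
      ", significant: ", sum(x$significant), "\n", sep = "")
  invisible(x)
}
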