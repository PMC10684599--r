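# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats qnorm pnorm pchisq pf rnorm rbinom runif median
#' quantile complete.cases coef sd var cor binomial glm.fit qchisq
NULL

# Least squares of y (vector or matrix) on X via QR.  Returns enough pieces
# for F tests; X must have full column rank unless allow_deficient.
.ols <- function(X, y, allow_deficient = FALSE) {
  qrx <- qr(X)
  if (!allow_deficient && qrx$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrx$rank)] %||% "unnamed"
    stop("design matrix is rank deficient; collinear columns include: ",
         paste(utils::tail(colnames(X), ncol(X) - qrx$rank), collapse = ", "))
  }
  res <- qr.resid(qrx, y)
  list(qr = qrx, coef = qr.coef(qrx, y), fitted = qr.fitted(qrx, y),
       resid = res, rank = qrx$rank,
       rss = if (is.matrix(y)) colSums(res^2) else sum(res^2))
}

# Covariate design matrix with intercept.  `covariates` may be NULL, a
# data.frame or a numeric matrix; all columns must be numeric.
.design <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  cm <- as.matrix(covariates)
  if (!is.numeric(cm)) stop("covariates must be numeric")
  if (nrow(cm) != n) stop("covariates have ", nrow(cm), " rows, expected ", n)
  if (is.null(colnames(cm))) colnames(cm) <- paste0("cov", seq_len(ncol(cm)))
  cbind(`(Intercept)` = 1, cm)
}

# Format a numeric vector so that read-back reproduces the doubles exactly.
.fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

# Apply .fmt_full to every double column of a data.frame (integers kept).
.fmt_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- .fmt_full(df[[j]])
  }
  df
}

.assert_prob <- function(x, name, lo = 0, hi = 1, open = TRUE) {
  ok <- if (open) all(x > lo & x < hi) else all(x >= lo & x <= hi)
  if (!all(is.finite(x)) || !ok) {
    stop(name, " must lie in ", if (open) "(" else "[", lo, ", ", hi,
         if (open) ")" else "]", call. = FALSE)
  }
  invisible(x)
}
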