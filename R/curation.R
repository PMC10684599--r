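#' Phenotype curation rules
#'
#' Thresholds governing phenotype cleaning and inclusion: continuous traits
#' are inverse rank-normalized when absolute skewness exceeds
#' `skewness_gate`, values beyond `outlier_sd` standard deviations from the
#' mean are set missing, and phenotypes with fewer than `min_cases` cases
#' (binary) or `min_observations` non-missing values (continuous) are
#' excluded from analysis.
#'
#' @param skewness_gate Absolute skewness above which the inverse normal
#'   transform is applied (default 0.75).
#' @param outlier_sd Outlier exclusion width in standard deviations
#'   (default 4).
#' @param min_cases Minimum case count for binary phenotypes (default 200;
#'   "fewer than 200" is read strictly, so exactly 200 cases is retained).
#' @param min_observations Minimum non-missing count for continuous
#'   phenotypes (default 200).
#' @return An object of class `curation_rules`.
#' @export
curation_rules <- function(skewness_gate = 0.75, outlier_sd = 4,
                           min_cases = 200, min_observations = 200) {
  stopifnot(skewness_gate > 0, outlier_sd > 0, min_cases > 0,
            min_observations > 0)
  structure(list(skewness_gate = skewness_gate, outlier_sd = outlier_sd,
                 min_cases = min_cases, min_observations = min_observations),
            class = "curation_rules")
}

#' Inverse rank-normal transform
#'
#' Maps the m non-missing values to normal quantiles of their rankit
#' offsets, `qnorm((rank - 0.5) / m)`, with average ranks for ties.
#' Missing values stay missing.  The output depends on the input only
#' through its ranks, so any strictly monotone rescaling of the input
#' yields an identical result.  A fully tied vector maps to all zeros
#' (every value sits at the median rank).
#'
#' @param values Numeric vector with at least two non-missing values.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' inverse_normal_transform(c(1, 2, 3))   # -0.967, 0, 0.967
inverse_normal_transform <- function(values) {
  ok <- !is.na(values)
  m <- sum(ok)
  if (m < 2L) stop("inverse normal transform needs at least 2 values")
  v <- values[ok]
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- qnorm((r - 0.5) / m)
  out
}

#' Curate one continuous phenotype
#'
#' Computes the adjusted Fisher-Pearson sample skewness; if its absolute
#' value exceeds the gate the inverse rank-normal transform is applied.
#' Values beyond `outlier_sd` standard deviations from the mean (assessed
#' after the transform when it fires, before otherwise) are then set
#' missing; the outlier step is iterated to its fixed point so that
#' curating curated output changes nothing.  Vectors left with fewer than
#' `min_observations` non-missing values are flagged excluded.
#'
#' @param values Numeric vector.
#' @param rules A [curation_rules()].
#' @return List with `values` (curated vector) and `log`, a list recording
#'   `skewness`, `transformed`, `n_outliers_excluded`, `n_nonmissing`, and
#'   `excluded`.
#' @export
curate_continuous <- function(values, rules = curation_rules()) {
  stopifnot(inherits(rules, "curation_rules"))
  skew <- if (sum(!is.na(values)) >= 3 &&
              length(unique(values[!is.na(values)])) > 1) {
    e1071::skewness(values, na.rm = TRUE, type = 2)
  } else NA_real_
  transformed <- isTRUE(abs(skew) > rules$skewness_gate)
  out <- if (transformed) inverse_normal_transform(values) else values
  n_out <- 0L
  repeat {
    mu <- mean(out, na.rm = TRUE)
    s <- sd(out, na.rm = TRUE)
    if (!is.finite(s) || s == 0) break
    drop <- which(!is.na(out) & abs(out - mu) > rules$outlier_sd * s)
    if (!length(drop)) break
    out[drop] <- NA_real_
    n_out <- n_out + length(drop)
  }
  n_ok <- sum(!is.na(out))
  list(values = out,
       log = list(skewness = skew, transformed = transformed,
                  n_outliers_excluded = n_out, n_nonmissing = n_ok,
                  excluded = n_ok < rules$min_observations))
}

#' Curate one binary phenotype
#'
#' Phenotypes with fewer than `min_cases` cases are flagged excluded;
#' others pass through unchanged.
#'
#' @param values Vector coded 0/1/NA.
#' @param rules A [curation_rules()].
#' @return List with `values` and `log` (`n_cases`, `n_controls`,
#'   `excluded`).
#' @export
curate_binary <- function(values, rules = curation_rules()) {
  stopifnot(inherits(rules, "curation_rules"))
  bad <- unique(values[!is.na(values) & !values %in% c(0, 1)])
  if (length(bad)) {
    stop("binary phenotype contains non-0/1 codes: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  n_cases <- sum(values == 1, na.rm = TRUE)
  list(values = values,
       log = list(n_cases = n_cases,
                  n_controls = sum(values == 0, na.rm = TRUE),
                  excluded = n_cases < rules$min_cases))
}

#' Aggregate diagnosis events into phecode case/control phenotypes
#'
#' An individual is a case for a phecode if at least one of their
#' primary-position diagnosis events maps to it; all other individuals in
#' the cohort are controls.  Unmapped codes are logged, not fatal.
#'
#' @param events Data frame with columns `individual`, `code`, `position`
#'   (events with `position == 1` are primary).
#' @param mapping Data frame with columns `code` and `phecode`.
#' @param individuals Vector of all individual ids defining the control
#'   set; defaults to the individuals present in `events`.
#' @return List with `phenotypes` (data frame of 0/1 columns, one per
#'   phecode, rownames = individuals) and `unmapped` (character vector of
#'   codes without a mapping).
#' @export
aggregate_phecodes <- function(events, mapping, individuals = NULL) {
  stopifnot(all(c("individual", "code", "position") %in% names(events)),
            all(c("code", "phecode") %in% names(mapping)))
  individuals <- individuals %||% unique(events$individual)
  prim <- events[events$position == 1, , drop = FALSE]
  idx <- match(prim$code, mapping$code)
  unmapped <- sort(unique(prim$code[is.na(idx)]))
  prim <- prim[!is.na(idx), , drop = FALSE]
  phe <- mapping$phecode[idx[!is.na(idx)]]
  all_phe <- sort(unique(mapping$phecode))
  out <- matrix(0L, length(individuals), length(all_phe),
                dimnames = list(as.character(individuals), all_phe))
  if (nrow(prim)) {
    ii <- match(prim$individual, individuals)
    keep <- !is.na(ii)
    out[cbind(ii[keep], match(phe[keep], all_phe))] <- 1L
  }
  list(phenotypes = as.data.frame(out), unmapped = unmapped)
}

#' Curate every phenotype in a cohort
#'
#' Applies [curate_continuous()] / [curate_binary()] to each phenotype and
#' drops the excluded ones from the analysis set.
#'
#' @param cohort A `bcaa_cohort`.
#' @param rules A [curation_rules()].
#' @return The cohort with `phenotypes` replaced by curated values,
#'   `phenotype_info` gaining `excluded`, `transformed` and `skewness`
#'   columns, and an added `curation` element with the per-phenotype logs.
#' @export
curate_cohort <- function(cohort, rules = curation_rules()) {
  stopifnot(inherits(cohort, "bcaa_cohort"))
  info <- cohort$phenotype_info
  logs <- vector("list", nrow(info))
  names(logs) <- info$name
  for (i in seq_len(nrow(info))) {
    nm <- info$name[i]
    cur <- if (info$kind[i] == "binary") {
      curate_binary(cohort$phenotypes[[nm]], rules)
    } else {
      curate_continuous(cohort$phenotypes[[nm]], rules)
    }
    cohort$phenotypes[[nm]] <- cur$values
    logs[[nm]] <- cur$log
  }
  info$excluded <- vapply(logs, function(l) l$excluded, TRUE)
  info$transformed <- vapply(logs, function(l) isTRUE(l$transformed), TRUE)
  info$skewness <- vapply(logs,
                          function(l) l$skewness %||% NA_real_, 0)
  cohort$phenotype_info <- info
  cohort$curation <- logs
  cohort
}
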