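#' Bonferroni threshold for a phenome-wide exposure scan
#'
#' `alpha / (n_phenotypes * n_exposures)`.  With 441 phenotypes and three
#' exposures at alpha 0.05 this is 3.78e-5.
#'
#' @param n_phenotypes Number of phenotypes analyzed.
#' @param n_exposures Number of exposures (default 3).
#' @param alpha Family-wise error rate (default 0.05).
#' @return The per-test significance threshold.
#' @export
#' @examples
#' bonferroni_threshold(441, 3)  # 3.78e-5
bonferroni_threshold <- function(n_phenotypes, n_exposures = 3,
                                 alpha = 0.05) {
  stopifnot(n_phenotypes > 0, n_exposures > 0)
  .assert_prob(alpha, "alpha")
  alpha / (n_phenotypes * n_exposures)
}

#' Classify phenotypes by per-method significance counts
#'
#' For each phenotype, counts how many exposures have `p < threshold`
#' under MVMR and under UVMR, cross-tabulates the two counts (rows UVMR
#' 0-3, columns MVMR 0-3, with margins), and flags the discordance
#' pattern in which UVMR reports several significant, directionally
#' homogeneous effects while the MVMR estimates for those same exposures
#' carry both signs.
#'
#' @param estimates A long `causal_estimate` table containing, for every
#'   phenotype, rows for all three exposures under both `MVMR` and `UVMR`.
#' @param threshold Significance threshold on the two-sided p-value.
#' @return An object of class `concordance_report`: list with
#'   `per_phenotype` (phenotype, category, `n_sig_mvmr`, `n_sig_uvmr`,
#'   sign-agreement flags), `crosstab` (4 x 4 integer matrix, UVMR rows by
#'   MVMR columns), `n_phenotypes` and `threshold`.
#' @export
classify_phenotypes <- function(estimates, threshold) {
  stopifnot(is.data.frame(estimates), threshold > 0)
  need <- c("phenotype", "exposure", "method", "beta", "p")
  miss <- setdiff(need, names(estimates))
  if (length(miss)) stop("estimates table lacks columns: ",
                         paste(miss, collapse = ", "))
  est <- estimates[estimates$method %in% c("MVMR", "UVMR"), ]
  phenos <- unique(est$phenotype)
  gaps <- character(0)
  per <- vector("list", length(phenos))
  for (i in seq_along(phenos)) {
    ph <- phenos[i]
    rows <- est[est$phenotype == ph, ]
    mv <- rows[rows$method == "MVMR", ]
    uv <- rows[rows$method == "UVMR", ]
    missing_mv <- setdiff(bcaa_names(), mv$exposure)
    missing_uv <- setdiff(bcaa_names(), uv$exposure)
    if (length(missing_mv) || length(missing_uv)) {
      gaps <- c(gaps, paste0(ph, ": missing ",
                             paste(c(if (length(missing_mv))
                                       paste0("MVMR/", missing_mv),
                                     if (length(missing_uv))
                                       paste0("UVMR/", missing_uv)),
                                   collapse = ", ")))
      next
    }
    mv <- mv[match(bcaa_names(), mv$exposure), ]
    uv <- uv[match(bcaa_names(), uv$exposure), ]
    mv_sig <- mv$p < threshold
    uv_sig <- uv$p < threshold
    sign_agree <- sign(mv$beta) == sign(uv$beta)
    uv_homog <- sum(uv_sig) >= 2 &&
      length(unique(sign(uv$beta[uv_sig]))) == 1L
    discordant <- uv_homog &&
      length(unique(sign(mv$beta[uv_sig]))) > 1L
    cat_col <- if ("category" %in% names(rows)) rows$category[1]
               else NA_character_
    per[[i]] <- data.frame(
      phenotype = ph, category = cat_col,
      n_sig_mvmr = sum(mv_sig), n_sig_uvmr = sum(uv_sig),
      sign_agree_leucine = sign_agree[1],
      sign_agree_isoleucine = sign_agree[2],
      sign_agree_valine = sign_agree[3],
      uvmr_homogeneous_mvmr_discordant = discordant,
      stringsAsFactors = FALSE
    )
  }
  if (length(gaps)) {
    stop("estimates incomplete for:\n  ", paste(gaps, collapse = "\n  "))
  }
  if (!length(per)) {
    per <- data.frame(phenotype = character(), category = character(),
                      n_sig_mvmr = integer(), n_sig_uvmr = integer(),
                      sign_agree_leucine = logical(),
                      sign_agree_isoleucine = logical(),
                      sign_agree_valine = logical(),
                      uvmr_homogeneous_mvmr_discordant = logical(),
                      stringsAsFactors = FALSE)
  } else {
    per <- do.call(rbind, per)
    per <- per[order(per$phenotype), , drop = FALSE]
  }
  rownames(per) <- NULL
  crosstab <- table(factor(per$n_sig_uvmr, levels = 0:3),
                    factor(per$n_sig_mvmr, levels = 0:3))
  crosstab <- matrix(as.integer(crosstab), 4, 4,
                     dimnames = list(uvmr = 0:3, mvmr = 0:3))
  structure(list(per_phenotype = per, crosstab = crosstab,
                 n_phenotypes = nrow(per), threshold = threshold),
            class = "concordance_report")
}

#' Headline percentages from a concordance cross-tabulation
#'
#' From a 4 x 4 cross-tabulation of significant-exposure counts (UVMR rows
#' by MVMR columns): the percentage of analyzed phenotypes with at least
#' one significant MVMR effect, and the percentage of those that are
#' significant for exactly one exposure.
#'
#' @param x A `concordance_report` or a 4 x 4 count matrix (UVMR rows by
#'   MVMR columns).
#' @return List with `n_total`, `n_any`, `n_single`, `pct_any`
#'   (100 * n_any / n_total) and `pct_single` (100 * n_single / n_any).
#' @export
concordance_percentages <- function(x) {
  ct <- if (inherits(x, "concordance_report")) x$crosstab else as.matrix(x)
  stopifnot(nrow(ct) == 4L, ncol(ct) == 4L)
  total <- sum(ct)
  mvmr_margin <- colSums(ct)
  n_any <- total - mvmr_margin[1]
  n_single <- mvmr_margin[2]
  list(n_total = total, n_any = unname(n_any),
       n_single = unname(n_single),
       pct_any = unname(100 * n_any / total),
       pct_single = if (n_any > 0) unname(100 * n_single / n_any) else NA_real_)
}

#' Published UK Biobank BCAA concordance counts
#'
#' The 4 x 4 cross-tabulation of significant-effect counts (univariable MR
#' rows by MVMR columns) reported by a published phenome-wide MVMR analysis
#' of the three BCAAs across 441 UK Biobank phenotypes.  Shipped as a
#' plain-text fixture; useful as a reference input for
#' [concordance_percentages()].
#'
#' @return 4 x 4 integer matrix with `uvmr`/`mvmr` dimnames.
#' @export
published_concordance_counts <- function() {
  path <- system.file("extdata", "ukb_bcaa_concordance_counts.tsv",
                      package = "bcaamvmr", mustWork = TRUE)
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  ct <- as.matrix(df[, c("mvmr_0", "mvmr_1", "mvmr_2", "mvmr_3")])
  dimnames(ct) <- list(uvmr = 0:3, mvmr = 0:3)
  storage.mode(ct) <- "integer"
  ct
}

#' Export a concordance report
#'
#' Writes the cross-tabulation, the per-phenotype classification and a run
#' manifest (seed, thresholds, software version) as plain-text files that
#' [read_summary()] can reproduce the report from.
#'
#' @param report A `concordance_report`.
#' @param directory Output directory (created if missing).
#' @param seed Optional seed to record in the manifest (e.g. the cohort
#'   seed, which regenerates the cohort bit-exactly).
#' @param config Optional `simulation_config` whose scalar settings are
#'   recorded in the manifest.
#' @return `directory`, invisibly.
#' @export
export_summary <- function(report, directory, seed = NULL, config = NULL) {
  stopifnot(inherits(report, "concordance_report"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  ct <- as.data.frame(report$crosstab)
  ct_wide <- data.frame(uvmr_count = 0:3,
                        mvmr_0 = report$crosstab[, 1],
                        mvmr_1 = report$crosstab[, 2],
                        mvmr_2 = report$crosstab[, 3],
                        mvmr_3 = report$crosstab[, 4])
  data.table::fwrite(ct_wide, file.path(directory, "crosstab.tsv"),
                     sep = "\t")
  data.table::fwrite(.fmt_df(report$per_phenotype),
                     file.path(directory, "per_phenotype.tsv"), sep = "\t",
                     na = "NA", quote = FALSE)
  manifest <- list(
    package = "bcaamvmr",
    version = as.character(utils::packageVersion("bcaamvmr")),
    threshold = report$threshold,
    n_phenotypes = report$n_phenotypes,
    seed = seed,
    config_seed = if (!is.null(config)) config$seed,
    n_individuals = if (!is.null(config)) config$n_individuals,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest[!vapply(manifest, is.null, TRUE)],
                       file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}

#' Read back an exported concordance report
#'
#' @param directory Directory written by [export_summary()].
#' @return A `concordance_report` (with the manifest attached as attribute
#'   `manifest`).
#' @export
read_summary <- function(directory) {
  ct_wide <- as.data.frame(
    data.table::fread(file.path(directory, "crosstab.tsv"), sep = "\t"))
  crosstab <- as.matrix(ct_wide[, c("mvmr_0", "mvmr_1", "mvmr_2",
                                    "mvmr_3")])
  dimnames(crosstab) <- list(uvmr = 0:3, mvmr = 0:3)
  storage.mode(crosstab) <- "integer"
  per <- as.data.frame(
    data.table::fread(file.path(directory, "per_phenotype.tsv"), sep = "\t",
                      na.strings = "NA"))
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"))
  structure(list(per_phenotype = per, crosstab = crosstab,
                 n_phenotypes = sum(crosstab),
                 threshold = manifest$threshold),
            class = "concordance_report", manifest = manifest)
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> ", x$n_phenotypes,
      " phenotypes, threshold ", signif(x$threshold, 3), "\n", sep = "")
  cat("cross-tabulation (rows UVMR count, columns MVMR count):\n")
  print(x$crosstab)
  pc <- concordance_percentages(x)
  cat(sprintf("%d phenotypes (%.1f%%) with >= 1 significant MVMR effect; ",
              pc$n_any, pc$pct_any))
  if (pc$n_any > 0) {
    cat(sprintf("%d (%.1f%%) with exactly one\n", pc$n_single,
                pc$pct_single))
  } else cat("\n")
  invisible(x)
}
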