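#' Run the full simulation-to-concordance pipeline
#'
#' Simulates a cohort, curates its phenotypes, runs per-exposure
#' genome-wide scans with genomic control and stepwise conditional signal
#' selection, builds cross-fitted polygenic-score instruments, fits MVMR,
#' univariable MR and observational estimates for every retained phenotype
#' on identical analysis samples, and classifies cross-method concordance
#' at the Bonferroni threshold.
#'
#' All randomness derives from `config$seed`; sub-seeds for fold
#' assignment and bootstraps are fixed offsets of it, so a single seed
#' reproduces the entire run.
#'
#' @param config A [simulation_config()]; defaults to the calibrated
#'   study-scale configuration.
#' @param rules Curation rules.
#' @param k_folds Cross-fitting folds for the instruments.
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @param n_boot Bootstrap replicates for probit standard errors.
#' @param gw_threshold Genome-wide significance threshold.
#' @param run_gwas Also run the per-exposure full-sample scans and
#'   stepwise conditional selection (default TRUE; the instruments run
#'   their own fold-level scans regardless).
#' @return List with `cohort`, `instruments`, `gwas` (per-exposure scan +
#'   independent signals, when `run_gwas`), `estimates` (long
#'   `causal_estimate` table), `threshold`, and `report`
#'   (a `concordance_report`).
#' @export
run_pipeline <- function(config = default_simulation_config(),
                         rules = curation_rules(), k_folds = 5,
                         alpha = 0.05, n_boot = 60,
                         gw_threshold = 1.7e-9, run_gwas = TRUE) {
  cohort <- simulate_cohort(config)
  cohort <- curate_cohort(cohort, rules)
  gwas <- NULL
  if (run_gwas) {
    gwas <- lapply(1:3, function(j) {
      scan <- scan_exposure(cohort, j, gw_threshold = gw_threshold)
      sig <- scan$variant[scan$significant]
      signals <- if (length(sig)) {
        stepwise_conditional(cohort, j, sig, p_threshold = gw_threshold)
      } else list(selected = character(0), conditional_p = numeric(0),
                  skipped_collinear = character(0))
      list(scan = scan, signals = signals)
    })
    names(gwas) <- bcaa_names()
  }
  instruments <- build_instruments(cohort, k_folds = k_folds,
                                   seed = config$seed + 1000L)
  info <- cohort$phenotype_info
  keep <- info$name[!info$excluded]
  est <- lapply(seq_along(keep), function(i) {
    fit_all_methods(cohort, instruments, keep[i], n_boot = n_boot,
                    boot_seed = config$seed + 2000L + i)
  })
  estimates <- as.data.frame(data.table::rbindlist(est, fill = TRUE))
  class(estimates) <- c("causal_estimate", "data.frame")
  threshold <- bonferroni_threshold(length(keep), 3, alpha)
  report <- classify_phenotypes(estimates, threshold)
  list(cohort = cohort, instruments = instruments, gwas = gwas,
       estimates = estimates, threshold = threshold, report = report)
}
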