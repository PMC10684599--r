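# Shared builders for compact test cohorts.

rc3 <- function(r) {
  m <- matrix(r, 3, 3)
  diag(m) <- 1
  m
}

# A small phenotype panel exercising mixed-sign, single-exposure,
# confounded-null and pure-null outcomes.
small_panel <- function() {
  list(
    phenotype_spec("mixed_trait", "Endocrine/metabolic", "continuous",
                   causal_betas = c(0.2, -0.15, 0.1), confounder_beta = 0.3,
                   noise_sd = 0.9),
    phenotype_spec("confounded_null", "Mental and behavioral disorders",
                   "continuous", causal_betas = c(0, 0, 0),
                   confounder_beta = 0.35, noise_sd = 0.9),
    phenotype_spec("pure_null", "Neurological", "continuous",
                   causal_betas = c(0, 0, 0), confounder_beta = 0,
                   noise_sd = 1),
    phenotype_spec("binary_trait", "Circulatory system", "binary",
                   causal_betas = c(0.3, -0.2, 0), confounder_beta = 0.3,
                   prevalence = 0.1)
  )
}

# Default-architecture cohort without the polygenic background: 8 shared +
# 4 valine-specific loci, calibrated correlations, a handful of nulls.
quick_config <- function(n = 20000, seed = 1,
                         phenotype_specs = small_panel(),
                         residual_correlation = rc3(0.95),
                         n_null_variants = 20, ...) {
  simulation_config(n_individuals = n,
                    n_background_loci = 0,
                    n_null_variants = n_null_variants,
                    residual_correlation = residual_correlation,
                    phenotype_specs = phenotype_specs,
                    seed = seed, ...)
}

quick_cohort <- function(n = 20000, seed = 1, ...) {
  simulate_cohort(quick_config(n = n, seed = seed, ...))
}
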