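#' Exposure names used throughout the package
#'
#' The three branched-chain amino acids, in the fixed order used by every
#' matrix and table in the package.
#'
#' @return Character vector of length three.
#' @export
bcaa_names <- function() c("leucine", "isoleucine", "valine")

#' Phenotype category vocabulary
#'
#' The seventeen phenotype categories used to label simulated and curated
#' phenotypes in phenome-wide summaries.
#'
#' @return Character vector of length 17.
#' @export
phenotype_categories <- function() {
  c("Circulatory system", "Dermatologic", "Digestive",
    "Endocrine/metabolic", "Genitourinary", "Hematopoietic",
    "Infectious diseases", "Medications",
    "Mental and behavioral disorders", "Musculoskeletal", "Neoplasms",
    "Neurological", "Other", "Reproductive", "Respiratory",
    "Sense organs", "Symptoms")
}

#' Specify one simulated phenotype
#'
#' Describes a single outcome in the simulated cohort: a continuous trait
#' with additive Gaussian noise, or a binary trait generated under a
#' liability-threshold (probit) model.  Causal effects are per standard
#' deviation of each standardized exposure, on the outcome scale for
#' continuous traits and on the latent liability scale for binary traits.
#'
#' @param name Phenotype identifier (syntactic name recommended).
#' @param category One of [phenotype_categories()].
#' @param kind `"continuous"` or `"binary"`.
#' @param causal_betas Numeric length-3 vector of per-SD causal effects of
#'   (leucine, isoleucine, valine).
#' @param confounder_beta Effect of the latent confounder on the outcome
#'   (liability scale for binary traits).
#' @param prevalence Case probability, binary traits only; in (0, 1).
#' @param noise_sd Residual standard deviation, continuous traits only.
#' @param liability_sd Standard deviation of the liability residual, binary
#'   traits only (default 1, the standard probit normalization).
#' @param covariate_beta Common nuisance effect of each observed covariate
#'   on the outcome (liability scale for binary traits).
#'
#' @return An object of class `phenotype_spec`.
#' @export
#' @examples
#' phenotype_spec("t2d", "Endocrine/metabolic", "binary",
#'                causal_betas = c(-0.12, 0, 0.15), confounder_beta = 0.25,
#'                prevalence = 0.046)
phenotype_spec <- function(name, category, kind,
                           causal_betas = c(0, 0, 0),
                           confounder_beta = 0,
                           prevalence = NULL,
                           noise_sd = NULL,
                           liability_sd = 1,
                           covariate_beta = 0.02) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!category %in% phenotype_categories()) {
    stop("unknown phenotype category: ", category)
  }
  kind <- match.arg(kind, c("continuous", "binary"))
  stopifnot(is.numeric(causal_betas), length(causal_betas) == 3L)
  if (kind == "binary") {
    if (is.null(prevalence) || !is.null(noise_sd)) {
      stop("binary phenotype '", name,
           "' must set prevalence and must not set noise_sd")
    }
    .assert_prob(prevalence, "prevalence")
    stopifnot(liability_sd > 0)
  } else {
    if (is.null(noise_sd) || !is.null(prevalence)) {
      stop("continuous phenotype '", name,
           "' must set noise_sd and must not set prevalence")
    }
    stopifnot(noise_sd > 0)
  }
  structure(list(name = name, category = category, kind = kind,
                 causal_betas = as.numeric(causal_betas),
                 confounder_beta = confounder_beta,
                 prevalence = prevalence, noise_sd = noise_sd,
                 liability_sd = liability_sd,
                 covariate_beta = covariate_beta),
            class = "phenotype_spec")
}

#' Default simulated phenotype panel
#'
#' A compact panel of continuous and binary phenotypes spanning several
#' phenotype categories, with per-exposure causal effects of mixed sign,
#' confounded-but-null phenotypes, and a pure null.  The panel exercises
#' every downstream estimator: distinct and opposing per-exposure effects,
#' effects mediated by a single exposure, purely confounded associations,
#' and absent effects.
#'
#' @return List of [phenotype_spec()] objects.
#' @export
default_phenotype_panel <- function() {
  list(
    phenotype_spec("type_2_diabetes", "Endocrine/metabolic", "binary",
                   causal_betas = c(-0.12, 0, 0.15), confounder_beta = 0.25,
                   prevalence = 0.046),
    phenotype_spec("diabetic_eye_disease", "Sense organs", "binary",
                   causal_betas = c(0, 0, 0.12), confounder_beta = 0.10,
                   prevalence = 0.012),
    phenotype_spec("angina", "Circulatory system", "binary",
                   causal_betas = c(0, 0.10, 0), confounder_beta = 0.20,
                   prevalence = 0.030),
    phenotype_spec("albuminuria", "Genitourinary", "binary",
                   causal_betas = c(0, 0, 0.10), confounder_beta = 0.15,
                   prevalence = 0.025),
    phenotype_spec("osteoporosis", "Musculoskeletal", "binary",
                   causal_betas = c(0, 0.10, -0.10), confounder_beta = -0.20,
                   prevalence = 0.012),
    phenotype_spec("chronic_bronchitis", "Respiratory", "binary",
                   causal_betas = c(0, -0.10, 0), confounder_beta = 0.15,
                   prevalence = 0.020),
    phenotype_spec("body_mass_index", "Endocrine/metabolic", "continuous",
                   causal_betas = c(0.15, -0.05, 0.10), confounder_beta = 0.30,
                   noise_sd = 0.90),
    phenotype_spec("egfr", "Genitourinary", "continuous",
                   causal_betas = c(-0.06, -0.06, -0.06),
                   confounder_beta = -0.20, noise_sd = 0.95),
    phenotype_spec("monocyte_pct", "Hematopoietic", "continuous",
                   causal_betas = c(0, 0.12, 0), confounder_beta = 0,
                   noise_sd = 0.95),
    phenotype_spec("grip_strength", "Musculoskeletal", "continuous",
                   causal_betas = c(0.10, 0, -0.08), confounder_beta = 0.10,
                   noise_sd = 0.90),
    phenotype_spec("depression_score", "Mental and behavioral disorders",
                   "continuous", causal_betas = c(0, 0, 0),
                   confounder_beta = 0.35, noise_sd = 0.90),
    phenotype_spec("reaction_time", "Neurological", "continuous",
                   causal_betas = c(0, 0, 0), confounder_beta = 0,
                   noise_sd = 1)
  )
}

#' Configure a synthetic cohort
#'
#' Defines the generative model for [simulate_cohort()]: three exposures
#' driven jointly by shared genetic loci, optional exposure-specific loci, a
#' polygenic background, a single latent standard-normal confounder, and
#' cross-correlated residual noise; plus observed nuisance covariates and a
#' phenotype panel.  Genetic effect vectors are constructed so that the
#' population genetic variance of each exposure equals its heritability
#' target exactly and the genetic correlation between exposures equals
#' `genetic_correlation` (deflated for exposures with specific loci).
#'
#' @param n_individuals Cohort size.
#' @param n_shared_loci Number of major loci affecting all three exposures.
#' @param n_specific_loci Integer length-3 vector of loci affecting one
#'   exposure only (may be 0; the default gives valine four extra loci).
#' @param n_background_loci Number of small-effect polygenic background
#'   variants shared across exposures.
#' @param n_null_variants Number of variants with no effect on any exposure.
#' @param maf_range Length-2 minor allele frequency range, within (0, 0.5].
#' @param heritability Length-3 narrow-sense heritability targets in
#'   `[0, 1)` for (leucine, isoleucine, valine).
#' @param genetic_correlation Correlation of per-locus standardized effects
#'   between exposures at shared and background loci.
#' @param specific_variance_fraction Length-3 fractions of each exposure's
#'   genetic variance carried by its specific loci; defaults to 0.05 for
#'   exposures with specific loci and 0 otherwise.
#' @param background_variance_fraction Fraction of each exposure's genetic
#'   variance carried by the polygenic background.
#' @param confounder_loading Length-3 loadings of the latent confounder on
#'   the exposures (SD units of exposure).
#' @param residual_correlation 3x3 positive-definite correlation matrix of
#'   the exposure residual noise.
#' @param covariate_effect Common nuisance effect of each observed covariate
#'   on each exposure.
#' @param quality_range Length-2 range of the per-variant imputation quality
#'   scalar.
#' @param phenotype_specs List of [phenotype_spec()] objects.
#' @param effect_matrix Optional explicit L x 3 matrix of standardized
#'   per-locus effects for the causal loci (rows in locus order: shared,
#'   then specific, then background).  Columns are rescaled so realized
#'   genetic variances still meet `heritability`; use this to build
#'   degenerate architectures such as one exposure's genetic value lying in
#'   the span of the others'.
#' @param seed Integer seed fixing all randomness of the cohort.
#'
#' @return An object of class `simulation_config`.
#' @seealso [default_simulation_config()] for the calibrated defaults.
#' @export
simulation_config <- function(n_individuals,
                              n_shared_loci = 8,
                              n_specific_loci = c(0, 0, 4),
                              n_background_loci = 0,
                              n_null_variants = 0,
                              maf_range = c(0.05, 0.45),
                              heritability = c(0.66, 0.65, 0.67),
                              genetic_correlation = 0.79,
                              specific_variance_fraction = NULL,
                              background_variance_fraction = 0,
                              confounder_loading = c(0.45, 0.45, 0.45),
                              residual_correlation = diag(3),
                              covariate_effect = 0.03,
                              quality_range = c(0.9, 1),
                              phenotype_specs = default_phenotype_panel(),
                              effect_matrix = NULL,
                              seed = 1L) {
  specific_variance_fraction <- specific_variance_fraction %||%
    ifelse(n_specific_loci > 0, 0.05, 0)
  stopifnot(n_individuals >= 2, n_shared_loci >= 3 || n_shared_loci == 0,
            length(n_specific_loci) == 3L,
            n_background_loci == 0 || n_background_loci >= 3,
            n_null_variants >= 0,
            length(maf_range) == 2L, length(heritability) == 3L,
            length(specific_variance_fraction) == 3L,
            length(confounder_loading) == 3L)
  .assert_prob(maf_range, "maf_range", lo = 0, hi = 0.5, open = FALSE)
  if (any(maf_range <= 0)) stop("maf_range must lie in (0, 0.5]")
  if (any(heritability < 0 | heritability >= 1)) {
    stop("heritability targets must lie in [0, 1)")
  }
  .assert_prob(abs(genetic_correlation), "abs(genetic_correlation)",
               open = FALSE)
  .assert_prob(specific_variance_fraction, "specific_variance_fraction",
               open = FALSE)
  .assert_prob(background_variance_fraction, "background_variance_fraction",
               open = FALSE)
  rc <- as.matrix(residual_correlation)
  if (!isTRUE(all.equal(dim(rc), c(3L, 3L))) || !isSymmetric(unname(rc)) ||
      any(abs(diag(rc) - 1) > 1e-12)) {
    stop("residual_correlation must be a symmetric 3x3 correlation matrix")
  }
  ev <- eigen(rc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("residual_correlation matrix is not positive definite ",
         "(smallest eigenvalue ", signif(min(ev), 3), ")")
  }
  if (any(specific_variance_fraction > 0 & n_specific_loci == 0)) {
    stop("specific_variance_fraction > 0 requires specific loci")
  }
  if (any(specific_variance_fraction + background_variance_fraction > 1)) {
    stop("specific plus background variance fractions must be <= 1")
  }
  if (!is.null(phenotype_specs)) {
    ok <- vapply(phenotype_specs, inherits, TRUE, what = "phenotype_spec")
    if (!all(ok)) stop("phenotype_specs must be phenotype_spec objects")
    nm <- vapply(phenotype_specs, `[[`, "", "name")
    if (anyDuplicated(nm)) stop("duplicate phenotype names")
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_shared_loci = as.integer(n_shared_loci),
    n_specific_loci = as.integer(n_specific_loci),
    n_background_loci = as.integer(n_background_loci),
    n_null_variants = as.integer(n_null_variants),
    maf_range = maf_range,
    heritability = heritability,
    genetic_correlation = genetic_correlation,
    specific_variance_fraction = specific_variance_fraction,
    background_variance_fraction = background_variance_fraction,
    confounder_loading = confounder_loading,
    residual_correlation = rc,
    covariate_effect = covariate_effect,
    quality_range = quality_range,
    phenotype_specs = phenotype_specs,
    effect_matrix = effect_matrix,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Calibrated default cohort configuration
#'
#' The study-scale default: eight shared loci plus four valine-specific
#' loci, a polygenic background, residual correlation 0.95 and confounder
#' loadings 0.45.  The calibration targets measured pairwise exposure
#' correlations of about 0.83-0.86, genetically predicted correlations of
#' about 0.75-0.79, and heritabilities of 0.65-0.67.
#'
#' @param n_individuals Cohort size (default 100,000).
#' @param seed Integer master seed.
#' @param phenotype_specs Phenotype panel; defaults to
#'   [default_phenotype_panel()].
#'
#' @return A `simulation_config`.
#' @export
default_simulation_config <- function(n_individuals = 1e5, seed = 1L,
                                      phenotype_specs =
                                        default_phenotype_panel()) {
  rc <- matrix(0.95, 3, 3); diag(rc) <- 1
  simulation_config(
    n_individuals = n_individuals,
    n_shared_loci = 8,
    n_specific_loci = c(0, 0, 4),
    n_background_loci = 600,
    n_null_variants = 188,
    heritability = c(0.66, 0.65, 0.67),
    genetic_correlation = 0.79,
    specific_variance_fraction = c(0, 0, 0.05),
    background_variance_fraction = 0.17,
    confounder_loading = c(0.45, 0.45, 0.45),
    residual_correlation = rc,
    phenotype_specs = phenotype_specs,
    seed = seed
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n",
      " individuals: ", x$n_individuals, "\n",
      " loci: ", x$n_shared_loci, " shared + ",
      paste(x$n_specific_loci, collapse = "/"), " specific + ",
      x$n_background_loci, " background + ",
      x$n_null_variants, " null\n",
      " heritability targets: ",
      paste(x$heritability, collapse = ", "), "\n",
      " genetic correlation: ", x$genetic_correlation, "\n",
      " phenotypes: ", length(x$phenotype_specs), "\n",
      " seed: ", x$seed, "\n", sep = "")
  invisible(x)
}
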