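#' Simulate a cohort of correlated exposures, genotypes and phenotypes
#'
#' Realizes the causal structure the estimators in this package are built
#' for: genetic variants G affect the outcomes only through the three
#' exposures X (so the exclusion restriction holds by construction), a
#' latent standard-normal confounder U affects all three exposures and the
#' outcomes, and exposure correlation is driven jointly by shared loci, the
#' confounder, and cross-correlated residual noise.
#'
#' Per-variant dosages are drawn Binomial(2, MAF) at linkage equilibrium.
#' Each exposure is the sum of its genetic value, `confounder_loading * U`,
#' small nuisance covariate effects, and correlated noise, then standardized
#' to unit sample variance.  Binary phenotypes arise by thresholding a
#' latent liability at the quantile matching the requested prevalence.
#'
#' @param config A [simulation_config()].
#' @return An object of class `bcaa_cohort`: a list with elements `dosages`
#'   (n x L matrix), `variant_info`, `exposures` (standardized n x 3),
#'   `exposures_raw`, `covariates`, `latent_confounder` (held out from
#'   analysis; available to tests), `phenotypes`, `phenotype_info`, and
#'   `truth` (the config plus realized per-variant effects, genetic values,
#'   liabilities and thresholds).
#' @export
#' @examples
#' cfg <- simulation_config(n_individuals = 500, n_background_loci = 0,
#'                          n_null_variants = 10, seed = 7)
#' ch <- simulate_cohort(cfg)
#' round(cor(ch$exposures), 2)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  n <- cfg$n_individuals
  exp_names <- bcaa_names()
  n_spec <- cfg$n_specific_loci
  L_causal <- cfg$n_shared_loci + sum(n_spec) + cfg$n_background_loci
  L <- L_causal + cfg$n_null_variants

  type <- c(rep("shared", cfg$n_shared_loci),
            rep(exp_names, times = n_spec),
            rep("background", cfg$n_background_loci),
            rep("null", cfg$n_null_variants))
  ids <- sprintf("var_%04d_%s", seq_len(L),
                 c(rep("sh", cfg$n_shared_loci),
                   rep(c("le", "il", "va"), times = n_spec),
                   rep("bg", cfg$n_background_loci),
                   rep("nu", cfg$n_null_variants)))

  maf <- runif(L, cfg$maf_range[1], cfg$maf_range[2])
  q <- runif(L, cfg$quality_range[1], cfg$quality_range[2])

  W <- .effect_matrix(cfg, L)            # L x 3, standardized-genotype scale
  sd_geno <- sqrt(2 * maf * (1 - maf))
  beta_allele <- W / sd_geno             # per-allele effects

  dosages <- matrix(rbinom(n * L, 2L, rep(maf, each = n)), n, L,
                    dimnames = list(NULL, ids))

  centered_g <- sweep(dosages %*% beta_allele, 2L,
                      colSums(2 * maf * beta_allele))
  colnames(centered_g) <- exp_names

  u <- rnorm(n)
  covariates <- data.frame(age = rnorm(n),
                           sex = rbinom(n, 1L, 0.5),
                           center = rnorm(n))
  cov_mat <- as.matrix(covariates)
  cov_eff <- cfg$covariate_effect
  # exact variance bookkeeping so total exposure variance is ~1 pre-scaling
  cov_var <- cov_eff^2 * (1 + 0.25 + 1)
  resid_var <- 1 - cfg$heritability - cfg$confounder_loading^2 - cov_var
  if (any(resid_var <= 0)) {
    stop("heritability, confounder loadings and covariate effects leave ",
         "no residual exposure variance")
  }
  sig_eps <- diag(sqrt(resid_var)) %*% cfg$residual_correlation %*%
    diag(sqrt(resid_var))
  eps <- matrix(rnorm(n * 3), n, 3) %*% chol(sig_eps)

  x_raw <- centered_g +
    tcrossprod(u, cfg$confounder_loading) +
    cov_mat %*% matrix(cov_eff, 3, 3) +
    eps
  colnames(x_raw) <- exp_names
  x_std <- scale(x_raw)
  attr(x_std, "scaled:center") <- NULL
  attr(x_std, "scaled:scale") <- NULL

  ph <- .simulate_phenotypes(cfg, x_std, u, cov_mat)

  variant_info <- data.frame(id = ids,
                             chrom = (seq_len(L) - 1L) %% 22L + 1L,
                             pos = seq_len(L) * 10000L,
                             maf = maf, q = q, type = type,
                             stringsAsFactors = FALSE)
  structure(list(
    dosages = dosages,
    variant_info = variant_info,
    exposures = x_std,
    exposures_raw = x_raw,
    covariates = covariates,
    latent_confounder = u,
    phenotypes = ph$values,
    phenotype_info = ph$info,
    truth = list(config = cfg, effects = W, effects_per_allele = beta_allele,
                 genetic_values = centered_g,
                 genetic_covariance = crossprod(W),
                 liabilities = ph$liabilities,
                 liability_thresholds = ph$thresholds,
                 residual_sd = sqrt(resid_var))
  ), class = "bcaa_cohort")
}

# Build the L x 3 matrix of standardized per-locus effects so that the
# population genetic covariance equals the configured target exactly:
# each block B satisfies B'B = Sigma_block via B = Q chol(Sigma_block) with
# Q column-orthonormal.
.effect_matrix <- function(cfg, L) {
  h <- cfg$heritability
  f <- cfg$specific_variance_fraction
  b <- cfg$background_variance_fraction
  a <- 1 - f - b                         # shared fraction per exposure
  rho <- cfg$genetic_correlation
  W <- matrix(0, L, 3)
  if (!is.null(cfg$effect_matrix)) {
    L_causal <- cfg$n_shared_loci + sum(cfg$n_specific_loci) +
      cfg$n_background_loci
    em <- as.matrix(cfg$effect_matrix)
    if (nrow(em) != L_causal || ncol(em) != 3L) {
      stop("effect_matrix must be ", L_causal, " x 3")
    }
    # rescale columns so Var(g_j) meets the heritability target
    for (j in 1:3) {
      s <- sum(em[, j]^2)
      if (h[j] > 0 && s == 0) stop("effect_matrix column ", j, " is all zero")
      if (s > 0) em[, j] <- em[, j] * sqrt(h[j] / s)
    }
    W[seq_len(L_causal), ] <- em
    return(W)
  }
  corr3 <- function() {m <- matrix(rho, 3, 3); diag(m) <- 1; m}
  block <- function(n_loci, var3) {
    out <- matrix(0, n_loci, 3)
    nz <- which(var3 > 0)
    if (!length(nz)) return(out)
    s <- sqrt(var3[nz])
    sig <- outer(s, s) * corr3()[nz, nz, drop = FALSE]
    qm <- qr.Q(qr(matrix(rnorm(n_loci * length(nz)), n_loci)))
    out[, nz] <- qm %*% chol(sig)
    out
  }
  at <- 0L
  if (cfg$n_shared_loci > 0 && any(h * a > 0)) {
    W[at + seq_len(cfg$n_shared_loci), ] <- block(cfg$n_shared_loci, h * a)
  }
  at <- at + cfg$n_shared_loci
  for (j in 1:3) {
    nj <- cfg$n_specific_loci[j]
    if (nj > 0 && h[j] * f[j] > 0) {
      z <- rnorm(nj)
      W[at + seq_len(nj), j] <- z / sqrt(sum(z^2)) * sqrt(h[j] * f[j])
    }
    at <- at + nj
  }
  if (cfg$n_background_loci > 0 && b > 0 && any(h > 0)) {
    W[at + seq_len(cfg$n_background_loci), ] <-
      block(cfg$n_background_loci, h * b)
  }
  W
}

.simulate_phenotypes <- function(cfg, x_std, u, cov_mat) {
  specs <- cfg$phenotype_specs
  n <- nrow(x_std)
  if (is.null(specs) || length(specs) == 0L) {
    return(list(values = data.frame(row.names = seq_len(n)),
                info = data.frame(name = character(), category = character(),
                                  kind = character()),
                liabilities = NULL, thresholds = NULL))
  }
  values <- vector("list", length(specs))
  liab <- list()
  thresholds <- numeric(0)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    lin <- drop(x_std %*% sp$causal_betas) + sp$confounder_beta * u +
      drop(cov_mat %*% rep(sp$covariate_beta, 3))
    if (sp$kind == "continuous") {
      values[[i]] <- lin + rnorm(n, 0, sp$noise_sd)
    } else {
      lb <- lin + rnorm(n, 0, sp$liability_sd)
      thr <- mean(lb) + qnorm(1 - sp$prevalence) * sd(lb)
      values[[i]] <- as.integer(lb > thr)
      liab[[sp$name]] <- lb
      thresholds[sp$name] <- thr
    }
  }
  names(values) <- vapply(specs, `[[`, "", "name")
  info <- data.frame(
    name = names(values),
    category = vapply(specs, `[[`, "", "category"),
    kind = vapply(specs, `[[`, "", "kind"),
    stringsAsFactors = FALSE
  )
  list(values = as.data.frame(values), info = info,
       liabilities = liab, thresholds = thresholds)
}

#' Append a noisy copy of an existing variant
#'
#' Emulates linkage disequilibrium by duplicating one variant's dosages,
#' resampling a fraction of individuals' genotypes from the population
#' frequency.  With `flip_prob = 0` the copy is exact (r-squared 1), which
#' is the degenerate case stepwise conditional selection must handle.
#'
#' @param cohort A `bcaa_cohort`.
#' @param variant Variant id or column index to copy.
#' @param flip_prob Fraction of individuals whose copied genotype is
#'   redrawn from Binomial(2, MAF).
#' @param id Name for the new variant (default `<variant>_copy`).
#' @param seed Seed for the resampling.
#' @return The cohort with one extra (non-causal for generation purposes,
#'   but correlated) variant.
#' @export
add_variant_copy <- function(cohort, variant, flip_prob = 0, id = NULL,
                             seed = 1L) {
  stopifnot(inherits(cohort, "bcaa_cohort"))
  j <- if (is.character(variant)) match(variant, colnames(cohort$dosages))
       else as.integer(variant)
  if (is.na(j) || j < 1L || j > ncol(cohort$dosages)) {
    stop("unknown variant: ", variant)
  }
  src <- colnames(cohort$dosages)[j]
  id <- id %||% paste0(src, "_copy")
  d <- cohort$dosages[, j]
  maf <- cohort$variant_info$maf[j]
  if (flip_prob > 0) {
    withr::with_seed(seed, {
      flip <- runif(length(d)) < flip_prob
      d[flip] <- rbinom(sum(flip), 2L, maf)
    })
  }
  cohort$dosages <- cbind(cohort$dosages, d)
  colnames(cohort$dosages)[ncol(cohort$dosages)] <- id
  new_row <- cohort$variant_info[j, ]
  new_row$id <- id
  new_row$type <- "ld_proxy"
  cohort$variant_info <- rbind(cohort$variant_info, new_row)
  rownames(cohort$variant_info) <- NULL
  cohort$truth$effects <- rbind(cohort$truth$effects, 0)
  cohort$truth$effects_per_allele <- rbind(cohort$truth$effects_per_allele, 0)
  cohort
}

#' @export
print.bcaa_cohort <- function(x, ...) {
  cat("<bcaa_cohort> n = ", nrow(x$dosages),
      ", variants = ", ncol(x$dosages),
      ", phenotypes = ", ncol(x$phenotypes), "\n", sep = "")
  cat("measured exposure correlations:\n")
  print(round(cor(x$exposures), 3))
  invisible(x)
}
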