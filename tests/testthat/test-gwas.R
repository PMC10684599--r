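# Association scan, QC filter, genomic control, stepwise selection.

test_that("effective sample size follows its closed form and QC gates", {
  expect_equal(effective_n(0.5, 1, 100), 50)
  expect_equal(effective_n(0.002, 0.4, 97469), 155.64, tolerance = 1e-3)
  expect_error(effective_n(0.6, 1, 100), "fold to the minor allele")
  # q = 0.4 with eff_n > 30 is retained; eff_n just under 30 is excluded
  expect_false(bcaamvmr:::.qc_excluded(0.002, 0.4, 97469))
  n_edge <- 29.99 / (2 * 0.1 * 0.9 * 1)
  expect_true(bcaamvmr:::.qc_excluded(0.1, 1, n_edge))
  expect_false(bcaamvmr:::.qc_excluded(0.1, 1, 30 / (2 * 0.1 * 0.9)))
  expect_true(bcaamvmr:::.qc_excluded(0.3, 0.39, 1e5))
})

test_that("scan betas and SEs match the per-variant lm oracle", {
  ch <- quick_cohort(n = 80, seed = 2, phenotype_specs = NULL)
  scan <- scan_exposure(ch, 1)
  y <- inverse_normal_transform(ch$exposures[, 1])
  cv <- ch$covariates
  for (v in c(1, 5, 17, 30)) {
    d <- ch$dosages[, v]
    fit <- summary(lm(y ~ d + age + sex + center, data = cv))
    expect_equal(scan$beta[v], fit$coefficients["d", 1],
                 tolerance = 1e-10)
    expect_equal(scan$se[v], fit$coefficients["d", 2], tolerance = 1e-10)
  }
})

test_that("monomorphic variants are flagged and not tested", {
  ch <- quick_cohort(n = 200, seed = 3, phenotype_specs = NULL)
  ch$dosages[, 2] <- 2L
  scan <- scan_exposure(ch, 1)
  expect_true(scan$monomorphic[2])
  expect_true(is.na(scan$beta[2]))
  expect_false(scan$significant[2])
})

test_that("null scans produce uniform p-values and calibrated lambda", {
  cfg <- simulation_config(n_individuals = 3000, n_shared_loci = 0,
                           n_specific_loci = c(0, 0, 0),
                           n_null_variants = 500,
                           heritability = c(0, 0, 0),
                           phenotype_specs = NULL, seed = 14)
  ch <- simulate_cohort(cfg)
  scan <- scan_exposure(ch, 2)
  p <- scan$p_raw[!scan$monomorphic]
  d_stat <- suppressWarnings(ks.test(p, "punif"))$statistic
  expect_lt(d_stat, 1.628 / sqrt(length(p)))  # alpha = 0.01 critical value
  expect_gt(attr(scan, "lambda"), 0.8)
  expect_lt(attr(scan, "lambda"), 1.25)
})

test_that("a strong causal variant passes genome-wide significance", {
  cfg <- simulation_config(
    n_individuals = 50000, n_shared_loci = 0,
    n_specific_loci = c(1, 0, 0), n_null_variants = 400,
    maf_range = c(0.3, 0.3),
    heritability = c(0.3^2 * 2 * 0.3 * 0.7, 0, 0),  # per-allele effect 0.3
    specific_variance_fraction = c(1, 0, 0),
    confounder_loading = c(0.3, 0.3, 0.3),
    phenotype_specs = NULL, seed = 15)
  ch <- simulate_cohort(cfg)
  expect_equal(abs(ch$truth$effects_per_allele[1, 1]), 0.3,
               tolerance = 1e-10)
  scan <- scan_exposure(ch, 1)
  expect_lt(scan$p_gc[1], 1.7e-9)
  expect_true(scan$significant[1])
})

test_that("genomic control uses the median reference and never deflates", {
  ref <- qchisq(0.5, 1)
  gc1 <- genomic_control(rep(ref, 11))
  expect_equal(gc1$lambda, 1)
  expect_equal(gc1$p_gc, rep(0.5, 11), tolerance = 1e-12)

  withr::with_seed(16, chi <- rchisq(2001, 1))
  chi <- chi * ref / median(chi)                # exactly lambda = 1
  base <- genomic_control(chi)
  doubled <- genomic_control(2 * chi)
  expect_equal(doubled$lambda, 2 * base$lambda, tolerance = 1e-12)
  expect_equal(doubled$p_gc, pchisq(chi, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  single <- genomic_control(5)
  expect_equal(single$lambda, 5 / ref, tolerance = 1e-12)

  deflate <- genomic_control(chi * 0.5)         # lambda 0.5 -> floored
  expect_equal(deflate$lambda_applied, 1)
  expect_equal(deflate$p_gc, pchisq(chi * 0.5, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(genomic_control(NA_real_), "at least one test")
})

test_that("stepwise selection keeps one of two exact duplicates", {
  cfg <- simulation_config(
    n_individuals = 5000, n_shared_loci = 0, n_specific_loci = c(1, 0, 0),
    n_null_variants = 10, heritability = c(0.25, 0, 0),
    specific_variance_fraction = c(1, 0, 0), phenotype_specs = NULL,
    seed = 17)
  ch <- simulate_cohort(cfg)
  causal <- ch$variant_info$id[1]
  ch <- add_variant_copy(ch, causal, flip_prob = 0)
  sel <- stepwise_conditional(ch, 1, c(causal, paste0(causal, "_copy")))
  expect_length(sel$selected, 1L)
  expect_identical(sel$skipped_collinear, setdiff(
    c(causal, paste0(causal, "_copy")), sel$selected))
})

test_that("two independent causal variants are both selected", {
  # equal variance shares at both loci, via an explicit effect matrix
  cfg <- simulation_config(
    n_individuals = 8000, n_shared_loci = 0, n_specific_loci = c(2, 0, 0),
    n_null_variants = 10, heritability = c(0.3, 0, 0),
    specific_variance_fraction = c(1, 0, 0), phenotype_specs = NULL,
    effect_matrix = cbind(c(1, 1), 0, 0), seed = 18)
  ch <- simulate_cohort(cfg)
  cands <- ch$variant_info$id[1:2]
  sel <- stepwise_conditional(ch, 1, c(cands, ch$variant_info$id[5:8]))
  expect_setequal(sel$selected, cands)
  # stopping contract: every returned signal stays conditionally significant
  expect_true(all(sel$conditional_p < 1.7e-9))
  # oracle: joint lm refit confirms both variants stay conditionally
  # genome-wide significant
  y <- inverse_normal_transform(ch$exposures[, 1])
  fit <- summary(lm(y ~ ch$dosages[, cands[1]] + ch$dosages[, cands[2]] +
                      age + sex + center, data = ch$covariates))
  p_joint <- fit$coefficients[2:3, 4]
  expect_true(all(p_joint < 1.7e-9))
})

test_that("selection stops when nothing clears the threshold", {
  ch <- quick_cohort(n = 1000, seed = 19, phenotype_specs = NULL)
  nulls <- ch$variant_info$id[ch$variant_info$type == "null"][1:5]
  sel <- stepwise_conditional(ch, 1, nulls)
  expect_length(sel$selected, 0L)
})
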