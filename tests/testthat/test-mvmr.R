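# First stage, Sanderson-Windmeijer conditional F, 2SLS, IV-probit.

cohort_mv <- quick_cohort(n = 20000, seed = 51)
inst_mv <- build_instruments(cohort_mv, k_folds = 5)

test_that("first-stage coefficients match the lm oracle on small data", {
  ch <- quick_cohort(n = 150, seed = 52, phenotype_specs = NULL)
  inst <- instrument_set(scale(matrix(rnorm(150 * 3), ncol = 3)))
  fs <- fit_first_stage(ch, inst)
  y <- inverse_normal_transform(ch$exposures[, 2])
  dat <- data.frame(y = y, ch$covariates, s1 = inst$scores[, 1],
                    s2 = inst$scores[, 2], s3 = inst$scores[, 3])
  fit <- lm(y ~ age + sex + center + s1 + s2 + s3, data = dat)
  expect_equal(unname(fs$coef[, 2]),
               unname(coef(fit)[c("(Intercept)", "age", "sex", "center",
                                  "s1", "s2", "s3")]),
               tolerance = 1e-10)
})

test_that("an exposure equal to one orthonormal score is fully explained", {
  ch <- quick_cohort(n = 1000, seed = 53, phenotype_specs = NULL)
  withr::with_seed(54, {
    qm <- qr.Q(qr(matrix(rnorm(1000 * 3), ncol = 3))) * sqrt(1000 - 1)
  })
  inst <- instrument_set(qm)
  ch$exposures[, 1] <- qm[, 1]
  ch$covariates <- NULL
  fs <- fit_first_stage(ch, inst, covariates = NULL, normalize = FALSE)
  expect_equal(unname(fs$coef[2:4, 1]), c(1, 0, 0), tolerance = 1e-8)
  expect_gt(fs$f_individual[1], 1e6)
})

test_that("single-exposure conditional F reduces to the individual F", {
  fs1 <- fit_first_stage(cohort_mv, inst_mv, exposures = 2)
  expect_equal(unname(fs1$sw_f), unname(fs1$f_individual),
               tolerance = 1e-12)
})

test_that("a conditionally redundant exposure is caught by SW F only", {
  em <- withr::with_seed(55, matrix(rnorm(8 * 3), 8, 3))
  em[, 1] <- 0.5 * (em[, 2] + em[, 3])   # exposure 1 genetics in the span
  cfg <- simulation_config(
    n_individuals = 10000, n_shared_loci = 8, n_specific_loci = c(0, 0, 0),
    n_null_variants = 20, heritability = c(0.6, 0.6, 0.6),
    specific_variance_fraction = c(0, 0, 0),
    residual_correlation = rc3(0.3), phenotype_specs = NULL,
    effect_matrix = em, seed = 56)
  ch <- simulate_cohort(cfg)
  inst <- build_instruments(ch, k_folds = 5)
  fs <- fit_first_stage(ch, inst)
  # genetics are rank 2, so individual strength is excellent for all
  # three exposures while conditional strength collapses
  expect_true(all(fs$f_individual > 10))
  expect_lt(fs$sw_f[1], 10)
})

test_that("2SLS equals the closed-form just-identified IV solution", {
  for (s in 1:10) {
    ch <- quick_cohort(n = 200, seed = 600 + s, phenotype_specs = NULL)
    withr::with_seed(700 + s, {
      sc <- scale(ch$truth$genetic_values +
                    matrix(rnorm(200 * 3, sd = 0.3), ncol = 3))
      y <- rnorm(200)
    })
    inst <- instrument_set(sc)
    est <- suppressWarnings(fit_mvmr_linear(ch, inst, y, normalize = FALSE))
    C <- cbind(1, as.matrix(ch$covariates))
    Zf <- cbind(C, sc)
    Xf <- cbind(C, ch$exposures)
    b_iv <- solve(crossprod(Zf, Xf), crossprod(Zf, y))
    expect_equal(est$beta, unname(b_iv[5:7]), tolerance = 1e-8)
  }
})

test_that("UVMR on one instrument reproduces the Wald ratio exactly", {
  y <- cohort_mv$phenotypes$mixed_trait
  est <- fit_uvmr(cohort_mv, inst_mv, 2, y)
  C <- cbind(1, as.matrix(cohort_mv$covariates))
  qrc <- qr(C)
  sr <- qr.resid(qrc, inst_mv$scores[, 2])
  xr <- qr.resid(qrc, inverse_normal_transform(cohort_mv$exposures[, 2]))
  yr <- qr.resid(qrc, y)
  expect_equal(est$beta, sum(sr * yr) / sum(sr * xr), tolerance = 1e-10)
})

test_that("a phenotype equal to an exposure is recovered as the identity", {
  y <- cohort_mv$exposures[, 2]
  est <- fit_mvmr_linear(cohort_mv, inst_mv, y, normalize = FALSE)
  expect_equal(est$beta, c(0, 1, 0), tolerance = 1e-8)
})

test_that("linear MVMR recovers mixed-sign truth within 3 SE", {
  est <- fit_mvmr_linear(cohort_mv, inst_mv, "mixed_trait")
  truth <- c(0.2, -0.15, 0.1)
  expect_true(all(abs(est$beta - truth) < 3 * est$se))
  expect_true(all(est$f_statistic > 10))
  expect_true(all(est$sw_f > 10))
  expect_true(all(est$ci_low < est$beta & est$beta < est$ci_high))
})

test_that("probit MVMR recovers the attenuated liability-scale truth", {
  est <- fit_mvmr_probit(cohort_mv, inst_mv, "binary_trait",
                         n_boot = 60, boot_seed = 57)
  fs <- attr(est, "first_stage")
  lb <- cohort_mv$truth$liabilities[["binary_trait"]]
  idx <- seq_along(lb)
  # projection oracle: regress the latent liability on the fitted
  # exposures; the probit truth is that slope over the residual SD
  xh <- fs$fitted
  proj <- lm(lb ~ xh + as.matrix(cohort_mv$covariates))
  gamma <- coef(proj)[2:4]
  sigma <- sd(resid(proj))
  expect_true(all(abs(est$beta - gamma / sigma) < 3 * est$se))
  expect_true(all(c("odds_ratio", "or_ci_low", "or_ci_high") %in%
                    names(est)))
  expect_equal(est$odds_ratio, exp(1.6 * est$beta), tolerance = 1e-12)
})

test_that("case-count and coding contracts are enforced", {
  expect_error(fit_mvmr_probit(cohort_mv, inst_mv,
                               rep(0, nrow(cohort_mv$exposures))),
               "fewer than 200")
  expect_error(fit_mvmr_probit(cohort_mv, inst_mv,
                               rep(c(0L, 1L), c(19900, 100))),
               "100 cases")
})

test_that("probit odds-ratio conversion follows the declared convention", {
  expect_equal(probit_to_or(0), 1)
  expect_equal(probit_to_or(0.5), exp(0.8), tolerance = 1e-12)
  b <- seq(-1, 1, by = 0.25)
  expect_true(all(diff(probit_to_or(b)) > 0))
  expect_equal(probit_to_or(0.5, factor = 1), exp(0.5))
})

test_that("collinear instruments are rejected naming the problem", {
  sc <- inst_mv$scores
  sc[, 3] <- sc[, 1]
  expect_error(fit_first_stage(cohort_mv, instrument_set(sc)),
               "rank deficient")
})

test_that("missing phenotype values are dropped per phenotype", {
  y <- cohort_mv$phenotypes$mixed_trait
  y[1:500] <- NA
  est <- fit_mvmr_linear(cohort_mv, inst_mv, y)
  expect_equal(unique(est$n_used), length(y) - 500)
})
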