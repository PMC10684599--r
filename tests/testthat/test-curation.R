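# Inverse rank-normal transform, outlier/skewness/case-count rules,
# phecode aggregation.

test_that("inverse normal transform matches its rankit quantiles", {
  expect_equal(inverse_normal_transform(c(1, 2, 3)),
               qnorm(c(0.5, 1.5, 2.5) / 3), tolerance = 1e-12)
  expect_equal(round(inverse_normal_transform(c(1, 2, 3)), 4),
               c(-0.9674, 0, 0.9674))
})

test_that("transform is invariant to strictly monotone rescaling", {
  withr::with_seed(1, x <- rexp(500))
  for (f in list(function(v) 3 * v - 7, exp, function(v) v^3)) {
    expect_equal(inverse_normal_transform(f(x)),
                 inverse_normal_transform(x), tolerance = 1e-12)
  }
})

test_that("ties get average ranks; degenerate inputs behave", {
  expect_equal(inverse_normal_transform(c(5, 5)), c(0, 0))
  # tied pair at average rank 2.5 of 4 -> qnorm(2/4) = 0
  expect_equal(inverse_normal_transform(c(1, 2, 2, 9))[2:3], c(0, 0))
  expect_equal(inverse_normal_transform(c(4, 4, 4)), c(0, 0, 0))
  expect_error(inverse_normal_transform(c(1, NA)), "at least 2")
  na_in <- c(1, NA, 2, 3)
  expect_identical(is.na(inverse_normal_transform(na_in)), is.na(na_in))
})

test_that("near-normal input is passed through with rare outlier loss", {
  withr::with_seed(10, x <- rnorm(10000))
  cur <- curate_continuous(x)
  expect_false(cur$log$transformed)
  # analytic exclusion count: Binomial(1e4, 2*pnorm(-4)) -> <= 5 whp
  expect_lte(cur$log$n_outliers_excluded, 5)
  expect_false(cur$log$excluded)
})

test_that("skewed input triggers the transform and normalizes moments", {
  withr::with_seed(11, x <- rexp(5000))
  cur <- curate_continuous(x)
  expect_true(cur$log$transformed)
  expect_gt(cur$log$skewness, 0.75)
  expect_lt(abs(e1071::skewness(cur$values, na.rm = TRUE, type = 2)), 0.1)
})

test_that("normality of the transform holds across input shapes", {
  gens <- list(function(n) rlnorm(n), function(n) runif(n),
               function(n) rt(n, df = 3), function(n) -rexp(n))
  for (i in seq_along(gens)) {
    withr::with_seed(100 + i, x <- gens[[i]](2000))
    out <- inverse_normal_transform(x)
    expect_lt(abs(e1071::skewness(out, type = 2)), 0.1)
  }
})

test_that("curation is idempotent", {
  withr::with_seed(12, {
    x_skew <- rexp(3000)
    x_norm <- rnorm(3000)
  })
  for (x in list(x_skew, x_norm)) {
    once <- curate_continuous(x)
    twice <- curate_continuous(once$values)
    expect_equal(twice$values, once$values, tolerance = 1e-12)
    expect_equal(twice$log$n_outliers_excluded, 0)
  }
  y <- rep(c(0, 1), c(500, 300))
  expect_identical(curate_binary(curate_binary(y)$values)$values, y)
})

test_that("observation and case-count gates follow the strict rule", {
  withr::with_seed(13, x <- rnorm(150))
  expect_true(curate_continuous(x)$log$excluded)
  expect_true(curate_binary(rep(c(1, 0), c(199, 5000)))$log$excluded)
  expect_false(curate_binary(rep(c(1, 0), c(200, 5000)))$log$excluded)
  all0 <- curate_binary(rep(0, 1000))
  expect_true(all0$log$excluded)
  expect_identical(all0$log$n_cases, 0L)
  expect_error(curate_binary(c(0, 1, 2)), "non-0/1")
})

test_that("phecode aggregation respects primary position and mapping", {
  mapping <- data.frame(code = c("E11.9", "I20.0", "M81.0"),
                        phecode = c("250.2", "411.1", "743.1"))
  events <- data.frame(
    individual = c("a", "a", "b", "c", "d"),
    code = c("E11.9", "I20.0", "I20.0", "E11.9", "ZZZ"),
    position = c(1, 2, 1, 2, 1))
  res <- aggregate_phecodes(events, mapping,
                            individuals = c("a", "b", "c", "d", "e"))
  ph <- res$phenotypes
  expect_identical(ph["a", "250.2"], 1L)  # primary event maps
  expect_identical(ph["a", "411.1"], 0L)  # secondary position only
  expect_identical(ph["b", "411.1"], 1L)
  expect_identical(ph["c", "250.2"], 0L)  # non-primary only -> control
  expect_identical(unname(unlist(ph["e", ])), c(0L, 0L, 0L))
  expect_identical(res$unmapped, "ZZZ")
  empty <- aggregate_phecodes(events[0, ], mapping,
                              individuals = c("a", "b"))
  expect_true(all(empty$phenotypes == 0))
})

test_that("the toy ICD-10 mapping fixture drives aggregation end to end", {
  mapping <- read.delim(system.file("extdata", "icd10_phecode_toy.tsv",
                                    package = "bcaamvmr"))
  expect_gte(nrow(mapping), 30)
  events <- data.frame(individual = c("p1", "p2", "p3"),
                       code = c("E11.9", "M81.0", "J40"),
                       position = 1)
  res <- aggregate_phecodes(events, mapping,
                            individuals = paste0("p", 1:4))
  expect_identical(res$phenotypes["p2", "743.1"], 1L)
  expect_length(res$unmapped, 0)
})

test_that("curate_cohort drops excluded phenotypes from the analysis set", {
  ch <- quick_cohort(n = 3000, seed = 30, phenotype_specs = list(
    phenotype_spec("rare", "Neoplasms", "binary", prevalence = 0.01),
    phenotype_spec("common", "Circulatory system", "binary",
                   prevalence = 0.2),
    phenotype_spec("skewed", "Digestive", "continuous", noise_sd = 1)))
  # make 'skewed' genuinely skewed post hoc
  ch$phenotypes$skewed <- exp(ch$phenotypes$skewed)
  cur <- curate_cohort(ch)
  info <- cur$phenotype_info
  expect_true(info$excluded[info$name == "rare"])     # ~30 cases < 200
  expect_false(info$excluded[info$name == "common"])
  expect_true(info$transformed[info$name == "skewed"])
})
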