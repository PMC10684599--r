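# Bonferroni threshold, concordance classification, exports.

make_est <- function(phenotype, method, betas, ps, category = "Other") {
  data.frame(phenotype = phenotype, category = category,
             exposure = bcaa_names(), method = method,
             beta = betas, p = ps, stringsAsFactors = FALSE)
}

test_that("bonferroni threshold follows its arithmetic", {
  expect_equal(signif(bonferroni_threshold(441, 3, 0.05), 3), 3.78e-5)
  expect_equal(bonferroni_threshold(1, 1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(10, 3, 0.05), 1.667e-3,
               tolerance = 1e-3)
  th <- sapply(c(10, 50, 441), bonferroni_threshold, n_exposures = 3)
  expect_true(all(diff(th) < 0))
  th2 <- sapply(1:3, function(k) bonferroni_threshold(100, k))
  expect_true(all(diff(th2) < 0))
})

test_that("all-null estimates land every phenotype in cell (0, 0)", {
  est <- rbind(make_est("a", "MVMR", c(1, 1, 1), rep(1, 3)),
               make_est("a", "UVMR", c(1, 1, 1), rep(1, 3)),
               make_est("b", "MVMR", c(-1, 1, -1), rep(1, 3)),
               make_est("b", "UVMR", c(1, -1, 1), rep(1, 3)))
  rep0 <- classify_phenotypes(est, 0.05)
  expect_equal(rep0$crosstab["0", "0"], 2L)
  expect_equal(sum(rep0$crosstab), 2L)
})

test_that("a hand-built fixture reproduces its enumerated cross-tab", {
  sig <- 1e-6; ns <- 0.5
  est <- rbind(
    # p1: MVMR 2 sig, UVMR 3 sig (homogeneous +, MVMR signs differ)
    make_est("p1", "MVMR", c(0.3, -0.2, 0.1), c(sig, sig, ns)),
    make_est("p1", "UVMR", c(0.2, 0.2, 0.1), c(sig, sig, sig)),
    # p2: nothing significant
    make_est("p2", "MVMR", c(0.1, 0.1, 0.1), rep(ns, 3)),
    make_est("p2", "UVMR", c(0.1, 0.1, 0.1), rep(ns, 3)),
    # p3: MVMR 1, UVMR 0
    make_est("p3", "MVMR", c(0.5, 0, 0), c(sig, ns, ns)),
    make_est("p3", "UVMR", c(0.4, 0.1, 0), rep(ns, 3)),
    # p4: MVMR 3, UVMR 3, both homogeneous (concordant pattern)
    make_est("p4", "MVMR", c(0.4, 0.3, 0.2), rep(sig, 3)),
    make_est("p4", "UVMR", c(0.3, 0.3, 0.3), rep(sig, 3)),
    # p5: MVMR 0, UVMR 2
    make_est("p5", "MVMR", c(0.1, 0.1, 0), rep(ns, 3)),
    make_est("p5", "UVMR", c(-0.2, -0.3, -0.1), c(sig, sig, ns)),
    # p6: MVMR 1, UVMR 1
    make_est("p6", "MVMR", c(0, 0.2, 0), c(ns, sig, ns)),
    make_est("p6", "UVMR", c(0, 0.2, 0), c(ns, sig, ns))
  )
  rep6 <- classify_phenotypes(est, 1e-3)
  expected <- matrix(0L, 4, 4, dimnames = list(uvmr = 0:3, mvmr = 0:3))
  expected["3", "2"] <- 1L  # p1
  expected["0", "0"] <- 1L  # p2
  expected["0", "1"] <- 1L  # p3
  expected["3", "3"] <- 1L  # p4
  expected["2", "0"] <- 1L  # p5
  expected["1", "1"] <- 1L  # p6
  expect_identical(rep6$crosstab, expected)
  per <- rep6$per_phenotype
  expect_true(per$uvmr_homogeneous_mvmr_discordant[per$phenotype == "p1"])
  expect_false(per$uvmr_homogeneous_mvmr_discordant[per$phenotype == "p4"])
  # classification is invariant to row order
  rep_sh <- classify_phenotypes(est[sample(nrow(est)), ], 1e-3)
  expect_identical(rep_sh$crosstab, rep6$crosstab)
  expect_identical(rep_sh$per_phenotype, rep6$per_phenotype)
  # missing rows are an error listing the gap
  expect_error(classify_phenotypes(est[-1, ], 1e-3), "p1.*MVMR/leucine")
})

test_that("published counts reproduce the headline percentages", {
  ct <- published_concordance_counts()
  expect_equal(sum(ct), 441L)
  pc <- concordance_percentages(ct)
  expect_equal(pc$n_any, 117)
  expect_equal(pc$n_single, 52)
  expect_equal(round(pc$pct_any, 1), 26.5)
  expect_equal(round(pc$pct_single), 44)
})

test_that("export and read-back reproduce a report with its manifest", {
  est <- rbind(make_est("a", "MVMR", c(0.3, 0, 0), c(1e-9, 0.4, 0.8)),
               make_est("a", "UVMR", c(0.3, 0.2, 0.2), c(1e-9, 1e-9, 0.3)))
  rep1 <- classify_phenotypes(est, 3.78e-5)
  dir <- withr::local_tempdir()
  export_summary(rep1, dir, seed = 123,
                 config = quick_config(n = 100, seed = 123))
  back <- read_summary(dir)
  expect_identical(back$crosstab, rep1$crosstab)
  expect_equal(back$threshold, rep1$threshold)
  expect_equal(back$per_phenotype$n_sig_mvmr, rep1$per_phenotype$n_sig_mvmr)
  manifest <- attr(back, "manifest")
  expect_equal(manifest$seed, 123)
  expect_equal(manifest$config_seed, 123)
})

test_that("an empty phenotype set exports zeroed margins", {
  est <- make_est("x", "MVMR", c(0, 0, 0), rep(1, 3))[0, ]
  rep0 <- classify_phenotypes(est, 0.05)
  expect_equal(sum(rep0$crosstab), 0L)
  expect_equal(rep0$n_phenotypes, 0L)
  dir <- withr::local_tempdir()
  export_summary(rep0, dir)
  back <- read_summary(dir)
  expect_identical(back$crosstab, rep0$crosstab)
  pc <- concordance_percentages(back)
  expect_equal(pc$n_any, 0)
})
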