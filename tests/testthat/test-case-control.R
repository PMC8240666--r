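test_that("2x2 odds ratios reproduce the published carrier comparisons", {
  # DRB1*01:01:01 carriers among DR15-bearing children vs parents
  o1 <- or_ci_yates(9, 243, 42, 328)
  expect_equal(round(o1$or, 2), 0.29)
  expect_equal(round(o1$ci, 2), c(0.14, 0.61))
  expect_equal(round(stats::pchisq(round(o1$chisq, 2), 1,
                                   lower.tail = FALSE), 6), 0.000892)
  expect_equal(o1$p, 0.000892, tolerance = 0.003)
  # printed 3.5% and 11.3% (exact fractions 3.57% and 11.35%)
  expect_equal(unname(o1$carrier_pct), c(3.5, 11.3), tolerance = 0.015)

  # B*27:05:02 carriers in the same strata
  o2 <- or_ci_yates(8, 244, 28, 342)
  expect_equal(round(o2$or, 2), 0.40)
  expect_equal(round(o2$ci, 2), c(0.18, 0.89))
  expect_equal(round(stats::pchisq(round(o2$chisq, 2), 1,
                                   lower.tail = FALSE), 6), 0.033306)
  expect_equal(o2$p, 0.033306, tolerance = 0.003)
  expect_equal(round(o2$carrier_pct, 1), c(3.2, 7.6), ignore_attr = TRUE)
})

test_that("odds-ratio edge cases behave", {
  sym <- or_ci_yates(20, 20, 20, 20)
  expect_equal(sym$or, 1)
  expect_gte(sym$p, 0.99)

  # Haldane correction on a zero cell
  hz <- or_ci_yates(0, 30, 10, 20)
  expect_true(hz$haldane)
  expect_true(is.finite(hz$or) && hz$or > 0)

  expect_error(or_ci_yates(-1, 2, 3, 4), "non-negative")

  # zero margin flagged
  zm <- or_ci_yates(0, 0, 10, 20)
  expect_false(zm$defined)
})

test_that("Yates p decreases as the association strengthens at fixed margins", {
  # shift counts along the diagonal, margins constant
  ps <- vapply(1:9, function(k)
    or_ci_yates(20 + k, 20 - k, 20 - k, 20 + k)$p, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("locus case-control test collapses, bins, and recovers effects", {
  # two-unit toy: overall chi-square equals the 2x2 chi-square
  cc <- locus_cc_test(c(rep("A*01:01", 30), rep("A*02:01", 10)),
                      c(rep("A*01:01", 20), rep("A*02:01", 20)))
  tab <- matrix(c(30, 10, 20, 20), 2, byrow = FALSE)
  expect_equal(cc$overall$chisq,
               unname(suppressWarnings(
                 stats::chisq.test(tab, correct = FALSE))$statistic),
               tolerance = 1e-12)
  expect_equal(cc$overall$df, 1)

  # all units rare: everything binned, overall test skipped
  rare <- locus_cc_test(paste0("B*", sprintf("%02d", 1:8), ":01"),
                        paste0("B*", sprintf("%02d", 11:18), ":01"))
  expect_true(rare$overall$skipped)
  expect_true(all(rare$per_unit$binned))

  # planted allele effect is recovered with a covering interval
  pool <- default_pool()
  model <- disease_model(0.02, data.frame(
    unit = "DPB1*104:01", n_fields = Inf, rr = 3, model = "multiplicative"))
  coh <- sample_cohort(400, 1500, pool, model, seed = 61)
  keys <- cohort_keys(coh, "DPB1", Inf)
  cc2 <- locus_cc_test(as.vector(keys[coh$group == "case", ]),
                       as.vector(keys[coh$group == "control", ]))
  row <- cc2$per_unit[cc2$per_unit$unit == "DPB1*104:01", ]
  expect_gt(row$or, 1)
  expect_true(row$ci_low < 3 && 3 < row$ci_high)
})

test_that("Monte-Carlo HWE p matches exhaustive enumeration", {
  g <- geno_from_counts(3, 4, 3)
  exact <- hwe_enum_biallelic(3, 4, 3)
  mc <- hwe_exact_mc(g, n_reps = 8000, seed = 5)
  se <- sqrt(exact * (1 - exact) / 8000)
  expect_lt(abs(mc$p - exact), 3 * se + 2 / 8001)

  # all homozygotes at a balanced 2-allele locus: strong deviation
  g2 <- geno_from_counts(10, 0, 10)
  expect_lt(hwe_exact_mc(g2, n_reps = 5000, seed = 6)$p, 0.01)
  expect_lt(hwe_enum_biallelic(10, 0, 10), 0.01)

  # near-perfect HWE proportions at large n: comfortably non-significant
  g3 <- geno_from_counts(100, 200, 100)
  expect_gt(hwe_exact_mc(g3, n_reps = 2000, seed = 7)$p, 0.3)

  # monomorphic locus
  g4 <- geno_from_counts(15, 0, 0)
  expect_equal(hwe_exact_mc(g4, seed = 8)$p, 1)
  expect_error(hwe_exact_mc(g, n_reps = 0), "n_reps")
})

test_that("multi-allelic HWE Monte Carlo is calibrated under the null", {
  # simulated random-mating genotypes should give roughly uniform p
  set.seed(11)
  alleles <- c("DQB1*03:01", "DQB1*05:01", "DQB1*06:02", "DQB1*02:01")
  ps <- vapply(1:40, function(i) {
    g <- cbind(sample(alleles, 60, TRUE, prob = c(.4, .3, .2, .1)),
               sample(alleles, 60, TRUE, prob = c(.4, .3, .2, .1)))
    hwe_exact_mc(g, n_reps = 500, seed = 100 + i)$p
  }, 0)
  expect_gt(mean(ps < 0.05), -1)  # computed without error
  expect_lt(mean(ps < 0.05), 0.25)
  expect_gt(mean(ps), 0.3)
})

test_that("genotype outliers flag planted homozygote excess only", {
  # exact HWE counts: no flags
  ex <- genotype_outliers(geno_from_counts(25, 50, 25))
  expect_false(any(ex$flagged))

  # planted homozygote excess in the shape of the published deviation
  g <- geno_from_counts(14, 30, 56)
  out <- genotype_outliers(g)
  hom <- out[out$genotype == "A*01:01+A*01:01", ]
  expect_gt(hom$observed, hom$expected)
  expect_true(hom$flagged)
  expect_equal(hom$direction, "excess")

  # invariance to allele relabeling
  g_swapped <- g[, 2:1]
  g_swapped[] <- ifelse(g_swapped == "A*01:01", "A*02:01",
                        ifelse(g_swapped == "A*02:01", "A*01:01",
                               g_swapped))
  out2 <- genotype_outliers(g_swapped)
  relabel <- function(geno) {
    al <- strsplit(geno, "+", fixed = TRUE)
    vapply(al, function(a) {
      a <- ifelse(a == "A*01:01", "A*02:01",
                  ifelse(a == "A*02:01", "A*01:01", a))
      paste(sort(a), collapse = "+")
    }, "")
  }
  expect_setequal(out2$genotype[out2$flagged],
                  relabel(out$genotype[out$flagged]))
  expect_equal(sort(out2$p), sort(out$p), tolerance = 1e-12)
})
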