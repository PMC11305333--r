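test_that("chi-square tail probabilities match their closed forms", {
  expect_equal(round(chisq_pvalue(0.52, 1), 2), 0.47)
  expect_lt(chisq_pvalue(14.8, 1), 0.001)
  for (k in c(1, 2, 5)) expect_equal(chisq_pvalue(0, k), 1)
  # df = 1 tail equals erfc(sqrt(x/2)) = 2 * P(Z > sqrt(x))
  for (x in seq(0.1, 30, length.out = 25)) {
    expect_equal(chisq_pvalue(x, 1),
                 2 * stats::pnorm(sqrt(x), lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_error(chisq_pvalue(-1, 1), "stat")
  expect_error(chisq_pvalue(1, 0), "df")
})

test_that("goodness-of-fit statistics match hand arithmetic", {
  perfect <- chisq_gof(c(75, 25), c(3, 1))
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p, 1)
  expect_equal(chisq_gof(c(90, 70), c(9, 7))$statistic, 0)
  off <- chisq_gof(c(60, 40), c(3, 1))
  expect_equal(off$statistic, 12.0) # (60-75)^2/75 + (40-25)^2/25
  expect_equal(off$df, 1L)
  expect_error(chisq_gof(c(1, 0), c(3, 1)), "pool")
  expect_error(chisq_gof(c(10, 10), c(3, -1)), "ratio")
})

test_that("uncorrected test keeps nominal type-I error at 3:1 truth", {
  withr::local_seed(101)
  o1 <- stats::rbinom(10000, 400, 0.75)
  stat <- (o1 - 300)^2 / 300 + ((400 - o1) - 100)^2 / 100
  rate <- mean(chisq_pvalue(stat, 1) < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("co-segregation verdicts follow the recessive model", {
  pop <- gen_f2_population("single_recessive", 2000, seed = 111)
  cs <- test_cosegregation(pop, "plA")
  expect_true(cs$recessive_consistent)
  expect_length(cs$violations, 0L)
  # duplicate-recessive: locus A alone cannot explain all mutants
  pop2 <- gen_f2_population("duplicate_recessive", 2000, seed = 112)
  cs2 <- test_cosegregation(pop2, "plA")
  expect_false(cs2$recessive_consistent)
  expect_gt(length(cs2$violations), 0L)
  viol <- pop2[pop2$id %in% cs2$violations, ]
  expect_true(all(viol$geno_plB[viol$phenotype == "trait_absent"] ==
                    "hom_alt"))
  # perfectly balanced 1:2:1 genotypes: no distortion signal
  pop3 <- data.frame(id = sprintf("i%03d", 1:400),
                     geno_plA = rep(c("hom_ref", "het", "hom_alt"),
                                    c(100, 200, 100)),
                     phenotype = rep(c("trait_present", "trait_absent"),
                                     c(300, 100)))
  cs3 <- test_cosegregation(pop3, "plA")
  expect_gt(cs3$distortion_result$p, 0.99)
  expect_equal(cs3$chi2_result$statistic, 0)
  # missing genotypes are excluded and counted
  pop$geno_plA[1:10] <- "missing"
  cs4 <- test_cosegregation(pop, "plA")
  expect_identical(cs4$n_missing, 10L)
  expect_error(test_cosegregation(pop, "nope"), "locus")
})

test_that("mendelian fractions match 1/4 and 7/16 expectations", {
  pop <- gen_f2_population("single_recessive", 10000, seed = 121)
  expect_equal(mean(pop$phenotype == "trait_absent"), 0.25,
               tolerance = 0.06)
  # exhaustive enumeration of the 9 two-locus classes: 7/16 mutant
  probs <- c(hom_ref = 1, het = 2, hom_alt = 1) / 4
  enum <- outer(probs, probs)
  mutant_mass <- sum(enum[rownames(enum) == "hom_alt", ]) +
    sum(enum[, colnames(enum) == "hom_alt"]) -
    enum["hom_alt", "hom_alt"]
  expect_equal(mutant_mass, 7 / 16)
  pop2 <- gen_f2_population("duplicate_recessive", 10000, seed = 122)
  expect_equal(mean(pop2$phenotype == "trait_absent"), mutant_mass,
               tolerance = 0.05)
  # with full penetrance every phenotypic mutant is homozygous somewhere
  mut <- pop2[pop2$phenotype == "trait_absent", ]
  expect_true(all(mut$geno_plA == "hom_alt" | mut$geno_plB == "hom_alt"))
})

test_that("genotype draws pass 1:2:1 goodness of fit across seeds", {
  pvals <- vapply(1:40, function(s) {
    pop <- gen_f2_population("single_recessive", 10000, seed = 1000 + s)
    counts <- table(factor(pop$geno_plA,
                           c("hom_ref", "het", "hom_alt")))
    chisq_gof(as.integer(counts), c(1, 2, 1))$p
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.98)
})

test_that("segregation distortion shifts genotype frequencies", {
  pop <- gen_f2_population("single_recessive", 10000, distortion = 0.5,
                           seed = 131)
  cs <- test_cosegregation(pop, "plA")
  expect_lt(cs$distortion_result$p, 0.001)
  expect_lt(mean(pop$geno_plA == "hom_alt"), 0.25)
})

test_that("model selection recovers generating phenotype ratios", {
  fit31 <- fit_segregation_model(c(2700, 900))
  expect_identical(attr(fit31, "best"), "3:1")
  fit97 <- fit_segregation_model(c(2025, 1575))
  expect_identical(attr(fit97, "best"), "9:7")
  expect_equal(fit97$p[1], 1) # 9/16 * 3600 = 2025 exactly
  expect_error(fit_segregation_model(c(8, 4)), "16")
  sel <- ratio_model_selection_experiment(n_seeds = 25, seed = 141)
  expect_gte(sel$selection_rate, 0.95)
})
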