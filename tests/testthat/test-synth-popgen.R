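# Three-population generator: allele frequencies, genotypes, phenotypes.

test_that("Balding-Nichols draws have the closed-form Beta moments", {
  set.seed(101)
  n <- 1e5
  # symmetric case: mean 0.5
  x <- balding_nichols_freq(0.5, 0.2, n)
  expect_lt(abs(mean(x) - 0.5), 4 * sqrt(0.5 * 0.5 * 0.2 / n))
  # variance reduces to rf (1 - rf) fst
  x <- balding_nichols_freq(0.3, 0.2, n)
  expect_lt(abs(mean(x) - 0.3), 4 * sqrt(0.3 * 0.7 * 0.2 / n))
  v_expect <- 0.3 * 0.7 * 0.2
  # 4-sigma Monte-Carlo bound on the sample variance via the fourth moment
  se_var <- sqrt((mean((x - mean(x))^4) - var(x)^2) / n)
  expect_lt(abs(var(x) - v_expect), 4 * se_var)
  expect_equal(v_expect, 0.042)
})

test_that("Balding-Nichols rejects degenerate parameters", {
  expect_error(balding_nichols_freq(0, 0.2), "rf")
  expect_error(balding_nichols_freq(1, 0.2), "rf")
  expect_error(balding_nichols_freq(0.5, 0), "fst")
  expect_error(balding_nichols_freq(0.5, 1), "fst")
})

test_that("allele-frequency table respects the category rules", {
  set.seed(102)
  tab <- draw_allele_frequencies(c(non_specific = 500))
  expect_equal(nrow(tab), 500)
  expect_true(all(tab$af_A == tab$af_B & tab$af_B == tab$af_C))

  tab <- draw_allele_frequencies(c(population_specific = 300))
  af <- as.matrix(tab[, c("af_A", "af_B", "af_C")])
  n_zero <- rowSums(af == 0)
  expect_true(all(n_zero == 2))
  carrier <- af[cbind(seq_len(300), match(tab$specific_pop, c("A", "B", "C")))]
  expect_true(all(carrier >= 0.4 & carrier <= 1))
  # half the carrier frequencies are exactly fixed, up to binomial noise
  expect_lt(abs(mean(carrier == 1) - 0.5), 4 * sqrt(0.25 / 300))
  # round-robin carrier assignment gives each population a third
  expect_equal(as.integer(table(tab$specific_pop)), c(100L, 100L, 100L))

  set.seed(103)
  tab <- draw_allele_frequencies(c(stratified = 2000))
  expect_true(all(tab$rf > 0 & tab$rf < 1))
  expect_true(all(af_cols <- unlist(tab[, c("af_A", "af_B", "af_C")]) >= 0))
  # per-population frequencies concentrate around rf more tightly at low Fst
  spread_A <- mean((tab$af_A - tab$rf)^2)  # Fst 0.02
  spread_C <- mean((tab$af_C - tab$rf)^2)  # Fst 0.2
  expect_gt(spread_C, 4 * spread_A)

  expect_equal(nrow(draw_allele_frequencies(c(non_specific = 0))), 0)
})

test_that("stratified frequencies match rf and rf(1-rf)Fst moments per SNP", {
  set.seed(104)
  n <- 2e4
  rf <- 0.37; fst <- 0.2
  x <- balding_nichols_freq(rf, fst, n)
  expect_lt(abs(mean(x) - rf), 4 * sqrt(rf * (1 - rf) * fst / n))
  se_var <- sqrt((mean((x - mean(x))^4) - var(x)^2) / n)
  expect_lt(abs(var(x) - rf * (1 - rf) * fst), 4 * se_var)
})

test_that("genotype sampling follows Hardy-Weinberg probabilities", {
  set.seed(105)
  # degenerate frequencies
  tab <- draw_allele_frequencies(c(population_specific = 3))
  g <- sample_genotypes(tab, rep(c("A", "B", "C"), each = 20))
  af <- as.matrix(tab[, c("af_A", "af_B", "af_C")])
  for (k in 1:3) {
    p <- tab$specific_pop[k]
    others <- setdiff(c("A", "B", "C"), p)
    expect_true(all(g$dosages[g$pop_labels %in% others, k] == 0))
    if (af[k, match(p, c("A", "B", "C"))] == 1)
      expect_true(all(g$dosages[g$pop_labels == p, k] == 2))
  }
  # HWE class proportions at af = 0.5, n = 1e4, within 4-sigma binomial bounds
  tab <- structure(data.frame(snp_id = "s1", category = "non_specific",
                              af_A = 0.5, af_B = 0.5, af_C = 0.5,
                              rf = NA_real_, specific_pop = NA_character_,
                              stringsAsFactors = FALSE),
                   class = c("af_table", "data.frame"))
  n <- 1e4
  g <- sample_genotypes(tab, rep("A", n))
  counts <- tabulate(g$dosages[, 1] + 1L, 3L)
  for (k in 1:3) {
    p <- c(0.25, 0.5, 0.25)[k]
    expect_lt(abs(counts[k] / n - p), 4 * sqrt(p * (1 - p) / n))
  }
  expect_true(all(g$dosages %in% 0:2))
  expect_equal(nrow(g$snp_meta), ncol(g$dosages))
})

test_that("genotype sampling rejects unknown population labels", {
  tab <- draw_allele_frequencies(c(non_specific = 2))
  expect_error(sample_genotypes(tab, c("A", "D")), "unknown population")
})

test_that("phenotype = genetic + environmental components at the target h2", {
  set.seed(106)
  af <- draw_allele_frequencies(c(non_specific = 100, population_specific = 100,
                                  stratified = 300))
  g <- sample_genotypes(af, sample(c("A", "B", "C"), 3000, replace = TRUE))
  ph <- simulate_phenotype(g, af, h2 = 0.6)
  expect_equal(ph$y, ph$y_genetic + ph$y_env)
  # causal counts: round(0.1 * count) per category
  expect_equal(as.integer(table(ph$causal$category)[c("non_specific",
                                                      "population_specific",
                                                      "stratified")]),
               c(10L, 10L, 30L))
  # h2 = 1 removes the environmental component entirely
  ph1 <- simulate_phenotype(g, af, h2 = 1)
  expect_true(all(ph1$y_env == 0))
  expect_equal(ph1$y, ph1$y_genetic)
})

test_that("environmental variance follows sigma^2_Yg (1 - h2) / h2", {
  set.seed(107)
  af <- draw_allele_frequencies(c(non_specific = 200))
  g <- sample_genotypes(af, rep("A", 3e4))
  ph <- simulate_phenotype(g, af, h2 = 0.6)
  ratio <- var(ph$y_env) / var(ph$y_genetic)
  expect_lt(abs(ratio - (1 - 0.6) / 0.6), 0.03)
})

test_that("realized heritability tracks h2 at moderate cohort size", {
  set.seed(108)
  af <- draw_allele_frequencies(c(non_specific = 70, population_specific = 70,
                                  stratified = 60))
  g <- sample_genotypes(af, sample(c("A", "B", "C"), 1e4, replace = TRUE))
  ph <- simulate_phenotype(g, af, h2 = 0.6)
  r2 <- summary(lm(ph$y ~ ph$y_genetic))$r.squared
  expect_lt(abs(r2 - 0.6), 0.03)
})

test_that("monomorphic causal sets raise a degenerate-variance error", {
  tab <- structure(data.frame(snp_id = c("s1", "s2"), category = "non_specific",
                              af_A = 0, af_B = 0, af_C = 0, rf = NA_real_,
                              specific_pop = NA_character_,
                              stringsAsFactors = FALSE),
                   class = c("af_table", "data.frame"))
  g <- sample_genotypes(tab, rep("A", 50))
  expect_error(simulate_phenotype(g, tab, h2 = 0.6, causal_fraction = 1),
               "monomorphic")
})

test_that("cohort construction shares one architecture and honours composition", {
  cfg <- scenario_config(snp_counts = c(non_specific = 30,
                                        population_specific = 30,
                                        stratified = 40),
                         cohort_sizes = c(base = 300, calibration = 120,
                                          target = 90),
                         seed = 11)
  co <- build_cohorts(cfg)
  expect_equal(nrow(co$base$geno$dosages), 300)
  expect_equal(nrow(co$calibration$geno$dosages), 120)
  expect_equal(nrow(co$target$geno$dosages), 90)
  # one shared causal-effect vector across cohorts
  expect_identical(co$base$pheno$causal, co$target$pheno$causal)
  expect_identical(co$base$pheno$causal, co$calibration$pheno$causal)

  # extreme-minority composition
  cfg2 <- scenario_preset("composition-extreme",
                          cohort_sizes = c(base = 1000, calibration = 500,
                                           target = 400),
                          snp_counts = c(non_specific = 30,
                                         population_specific = 30,
                                         stratified = 40),
                          seed = 12)
  co2 <- build_cohorts(cfg2)
  expect_equal(mean(co2$base$geno$pop_labels == "C"), 0.03, tolerance = 0.01)
  expect_equal(mean(co2$target$geno$pop_labels == "C"), 0.97, tolerance = 0.01)

  # absent-population composition: no A in the target
  cfg3 <- scenario_preset("composition-absent",
                          cohort_sizes = c(base = 300, calibration = 150,
                                           target = 100),
                          snp_counts = c(non_specific = 30,
                                         population_specific = 30,
                                         stratified = 40),
                          seed = 13)
  co3 <- build_cohorts(cfg3)
  expect_equal(sum(co3$target$geno$pop_labels == "A"), 0)
  expect_gt(sum(co3$base$geno$pop_labels == "A"), 0)
})

test_that("identical seed and config reproduce cohorts bit for bit", {
  cfg <- scenario_config(snp_counts = c(non_specific = 20,
                                        population_specific = 20,
                                        stratified = 20),
                         cohort_sizes = c(base = 120, calibration = 60,
                                          target = 40),
                         seed = 99)
  a <- build_cohorts(cfg)
  b <- build_cohorts(cfg)
  expect_identical(a$base$geno$dosages, b$base$geno$dosages)
  expect_identical(a$target$pheno$y, b$target$pheno$y)
  expect_identical(a$af_table, b$af_table)
})

test_that("scenario config validation rejects bad inputs", {
  expect_error(scenario_config(snp_counts = c(non_specific = -1)), "non-negative")
  expect_error(scenario_config(cohort_sizes = c(base = 0, calibration = 10,
                                                target = 10)), "non-empty")
  expect_error(scenario_config(h2 = 0), "h2")
  expect_error(scenario_config(composition = list(
    base = c(A = 0.5, B = 0.5, C = 0.5),
    calibration = c(A = 1/3, B = 1/3, C = 1/3),
    target = c(A = 1/3, B = 1/3, C = 1/3))), "summing to 1")
  expect_error(scenario_preset("no-such-preset"), "unknown preset")
})
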