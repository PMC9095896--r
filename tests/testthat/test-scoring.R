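# PGS construction (clumping, thresholding) and PGS/AS computation.

make_gwas <- function(ids, chrom, pos, pvalue, beta = rnorm(length(ids))) {
  ancestryscore:::new_summary_stats(
    data.frame(id = ids, chrom = chrom, pos = pos, ref = "A", alt = "G",
               beta = beta, se = abs(beta) / 2, pvalue = pvalue,
               n = 1000, tested = TRUE, note = NA_character_,
               stringsAsFactors = FALSE),
    kind = "gwas")
}

test_that("clumping keeps the lowest-p SNP of a correlated pair", {
  set.seed(401)
  n <- 300
  shared <- rbinom(n, 2, 0.4)
  dos <- cbind(lead = shared, proxy = shared, indep = rbinom(n, 2, 0.4))
  g <- toy_geno(dos, pos = c(1e6, 1.001e6, 5e8))
  gw <- make_gwas(colnames(dos), 1L, c(1e6, 1.001e6, 5e8),
                  pvalue = c(1e-8, 1e-4, 0.2))
  out <- clump_snps(gw, g)
  expect_setequal(out, c("lead", "indep"))
})

test_that("mutually independent SNPs all survive clumping", {
  set.seed(402)
  g <- toy_geno(random_dosages(2000, 10))
  gw <- make_gwas(g$snp_meta$id, 1L, g$snp_meta$pos, pvalue = runif(10))
  expect_setequal(clump_snps(g = gw, ld_reference = g), g$snp_meta$id)
})

test_that("clumping matches an exhaustive reference on random instances", {
  for (seed in c(403, 404, 405)) {
    set.seed(seed)
    n <- 250; s <- 20
    # correlated blocks: successive SNPs share signal
    base1 <- rbinom(n, 2, 0.5); base2 <- rbinom(n, 2, 0.3)
    dos <- sapply(seq_len(s), function(i) {
      src <- if (i %% 3 == 0) base1 else if (i %% 3 == 1) base2 else rbinom(n, 2, 0.4)
      flip <- sample(n, 40)
      src[flip] <- rbinom(40, 2, 0.4)
      src
    })
    colnames(dos) <- sprintf("snp_%05d", 1:s)
    pos <- sort(sample(1:5e5, s)) + 1e6
    g <- toy_geno(dos, pos = pos)
    pv <- runif(s)
    gw <- make_gwas(colnames(dos), 1L, pos, pvalue = pv)
    expect_identical(clump_snps(gw, g, window_kb = 100, r2_cut = 0.1),
                     clump_reference(colnames(dos), rep(1L, s), pos, pv, dos,
                                     window_kb = 100, r2_cut = 0.1))
  }
})

test_that("threshold optimization prefers signal over noise", {
  set.seed(406)
  reps <- 15
  wins <- logical(reps)
  traces <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    n <- 600; s <- 50
    af <- runif(s, 0.1, 0.5)
    draw <- function(m) {
      d <- matrix(rbinom(m * s, 2L, rep(af, each = m)), m, s)
      colnames(d) <- sprintf("snp_%05d", 1:s); d
    }
    g_base <- toy_geno(draw(n))
    g_cal <- toy_geno(draw(n))
    beta_true <- 1.2
    y_base <- beta_true * g_base$dosages[, 1] + rnorm(n)
    y_cal <- beta_true * g_cal$dosages[, 1] + rnorm(n)
    gw <- run_gwas(g_base, y_base)
    f <- optimize_pgs_threshold(gw, gw$id[gw$tested], g_cal, y_cal,
                                thresholds = c(1e-8, 0.05, 1))
    traces[r, ] <- f$calibration_r2_by_threshold
    wins[r] <- f$p_threshold <= 0.05
  }
  # the causal-only threshold wins essentially always, and the held-out trace
  # degrades on average as noise-weighted null SNPs flood in
  expect_gt(mean(wins), 0.9)
  expect_gt(mean(traces[, 1] - traces[, 3]), 0)
})

test_that("threshold edge cases behave deterministically", {
  set.seed(407)
  g <- toy_geno(random_dosages(200, 6))
  y <- rnorm(200)
  gw <- run_gwas(g, y)
  # single threshold of 1 admits everything
  f <- optimize_pgs_threshold(gw, gw$id, g, y, thresholds = 1)
  expect_setequal(f$snp_ids, gw$id)
  # identical SNP sets at every threshold -> smallest threshold wins
  gw2 <- gw; gw2$pvalue <- rep(1e-10, 6)
  f2 <- optimize_pgs_threshold(gw2, gw2$id, g, y,
                               thresholds = c(0.01, 0.5, 1))
  expect_equal(f2$p_threshold, 0.01)
  # empty clumped set errors
  expect_error(optimize_pgs_threshold(gw, character(), g, y), "empty")
  expect_error(optimize_pgs_threshold(gw, gw$id, g, y, thresholds = c(0, 1)),
               "thresholds")
})

test_that("PGS is the weighted dosage sum", {
  dos <- rbind(c(2L, 1L, 1L), c(0L, 2L, 1L))
  colnames(dos) <- c("a", "b", "c")
  g <- toy_geno(dos)
  f <- structure(list(snp_ids = c("a", "b", "c"), effect_alleles = rep("G", 3),
                      weights = c(a = 0.5, b = -1, c = 2),
                      p_threshold = 1), class = "pgs_formula")
  sv <- compute_pgs(g, f)
  expect_equal(sv$value, c(0.5 * 2 - 1 + 2, -2 + 2))
  # linearity in the weights
  f2 <- f; f2$weights <- 2 * f$weights
  expect_equal(compute_pgs(g, f2)$value, 2 * sv$value)
  # single SNP with unit weight reproduces the dosage column
  f3 <- structure(list(snp_ids = "b", effect_alleles = "G",
                       weights = c(b = 1), p_threshold = 1),
                  class = "pgs_formula")
  expect_equal(compute_pgs(g, f3)$value, as.numeric(dos[, "b"]))
})

test_that("PGS over disjoint SNP sets is additive and column-order invariant", {
  set.seed(408)
  g <- toy_geno(random_dosages(30, 8))
  w <- rnorm(8); names(w) <- g$snp_meta$id
  mk <- function(ids) structure(list(snp_ids = ids, effect_alleles = "G",
                                     weights = w[ids], p_threshold = 1),
                                class = "pgs_formula")
  full <- compute_pgs(g, mk(g$snp_meta$id))
  part <- compute_pgs(g, mk(g$snp_meta$id[1:3]))$value +
    compute_pgs(g, mk(g$snp_meta$id[4:8]))$value
  expect_equal(full$value, part, tolerance = 1e-12)
  perm <- sample(8)
  gp <- ancestryscore:::new_genotype_dataset(
    g$dosages[, perm], g$sample_ids, g$pop_labels, g$snp_meta[perm, ])
  expect_equal(compute_pgs(gp, mk(g$snp_meta$id))$value, full$value,
               tolerance = 1e-12)
})

test_that("missing PGS SNPs: warn at <=5%, error above", {
  set.seed(409)
  g <- toy_geno(random_dosages(20, 30))
  w <- rep(1, 40)
  ids <- c(g$snp_meta$id, paste0("gone_", 1:10))
  names(w) <- ids
  f_many <- structure(list(snp_ids = ids, effect_alleles = "G", weights = w,
                           p_threshold = 1), class = "pgs_formula")
  expect_error(compute_pgs(g, f_many), "missing")
  ids2 <- c(g$snp_meta$id, "gone_1")
  f_one <- structure(list(snp_ids = ids2, effect_alleles = "G",
                          weights = setNames(rep(1, 31), ids2),
                          p_threshold = 1), class = "pgs_formula")
  expect_warning(sv <- compute_pgs(g, f_one), "missing")
  expect_equal(sv$value, rowSums(g$dosages))
})

test_that("AS is the mapped-PC / PCAS dot product", {
  mk_pcas <- function(betas) ancestryscore:::new_summary_stats(
    data.frame(id = paste0("PC", seq_along(betas)), beta = betas,
               se = 0.1, pvalue = 0.5, n = 100, tested = TRUE,
               note = NA_character_, stringsAsFactors = FALSE),
    kind = "pcas")
  pcs <- structure(list(sample_ids = c("s1", "s2"),
                        scores = rbind(c(0.3, 0.3), c(1, 2)),
                        source = "projected"), class = "mapped_pcs")
  expect_equal(compute_as(pcs, mk_pcas(c(1, -1)))$value, c(0, -1))
  expect_equal(compute_as(pcs, mk_pcas(c(0, 0)))$value, c(0, 0))
  pcs2 <- structure(list(sample_ids = "s1", scores = cbind(c(1, 2)),
                         source = "projected"), class = "mapped_pcs")
  expect_error(compute_as(pcs2, mk_pcas(c(2, 0.5))), "PCs")
  # arithmetic check on a 2-PC score
  pcs3 <- structure(list(sample_ids = "s1", scores = rbind(c(1, 2)),
                         source = "projected"), class = "mapped_pcs")
  expect_equal(compute_as(pcs3, mk_pcas(c(2, 0.5)))$value, 3)
})
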