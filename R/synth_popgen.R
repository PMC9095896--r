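# Three-population cohort simulator: Balding-Nichols allele frequencies,
# Hardy-Weinberg genotype sampling, heritability-controlled phenotypes.

POPS <- c("A", "B", "C")
SNP_CATEGORIES <- c("non_specific", "population_specific", "stratified")

#' Draw subpopulation allele frequencies under the Balding-Nichols model
#'
#' Given an ancestral (reference) allele frequency `rf` and a fixation index
#' `fst`, subpopulation alternate-allele frequencies are drawn from
#' \deqn{Af \sim Beta\left(\frac{Rf(1-F_{st})}{F_{st}},
#'                          \frac{(1-Rf)(1-F_{st})}{F_{st}}\right),}
#' which has mean `rf` and variance `rf (1 - rf) fst`. Larger `fst` therefore
#' means stronger drift of subpopulation frequencies away from the ancestral
#' value.
#'
#' @param rf Ancestral alternate-allele frequency, strictly in (0, 1).
#' @param fst Fixation index, strictly in (0, 1).
#' @param n Number of independent draws.
#' @return Numeric vector of `n` frequencies in (0, 1).
#' @examples
#' set.seed(1)
#' mean(balding_nichols_freq(0.5, 0.2, 1e4))  # ~0.5
#' @export
balding_nichols_freq <- function(rf, fst, n = 1L) {
  if (!is.numeric(rf) || length(rf) != 1L || !is.finite(rf) || rf <= 0 || rf >= 1)
    abort_validation("`rf` must be a single value strictly between 0 and 1 (Beta shape would be degenerate)")
  if (!is.numeric(fst) || length(fst) != 1L || !is.finite(fst) || fst <= 0 || fst >= 1)
    abort_validation("`fst` must be a single value strictly between 0 and 1")
  shape1 <- rf * (1 - fst) / fst
  shape2 <- (1 - rf) * (1 - fst) / fst
  rbeta(n, shape1, shape2)
}

#' Generate a per-category allele-frequency table for three populations
#'
#' Each SNP falls in one of three categories:
#' * `non_specific`: one frequency drawn from U(0, 1), shared by all three
#'   populations (no population structure at this SNP);
#' * `population_specific`: the alternate allele exists in exactly one
#'   population, where its frequency is, with equal probability, either drawn
#'   from U(0.4, 1) or fixed at 1; the other two populations get frequency 0.
#'   The carrier population rotates A, B, C, ... across such SNPs so each
#'   population carries about a third of them;
#' * `stratified`: an ancestral frequency Rf ~ U(0, 1) is drawn, then each
#'   population's frequency comes from [balding_nichols_freq()] at that
#'   population's Fst.
#'
#' @param snp_counts Named integer vector with entries `non_specific`,
#'   `population_specific` and `stratified` (missing entries default to 0).
#' @param fst Named numeric vector of per-population fixation indices for the
#'   stratified category; default `c(A = 0.02, B = 0.02, C = 0.2)`.
#' @return An `af_table` data.frame with columns `snp_id`, `category`,
#'   `af_A`, `af_B`, `af_C`, `rf` (stratified rows only) and `specific_pop`
#'   (population-specific rows only).
#' @export
draw_allele_frequencies <- function(snp_counts,
                                    fst = c(A = 0.02, B = 0.02, C = 0.2)) {
  counts <- setNames(integer(3L), SNP_CATEGORIES)
  if (length(snp_counts)) {
    bad <- setdiff(names(snp_counts), SNP_CATEGORIES)
    if (length(bad) || is.null(names(snp_counts)))
      abort_validation(paste0("unknown SNP categories: ",
                              paste(bad, collapse = ", ")))
    counts[names(snp_counts)] <- as.integer(snp_counts)
  }
  if (any(counts < 0)) abort_validation("SNP counts must be non-negative")
  if (!all(POPS %in% names(fst)) || any(fst <= 0 | fst >= 1))
    abort_validation("`fst` must name populations A, B, C with values in (0, 1)")

  rows <- list()
  if (counts[["non_specific"]] > 0) {
    k <- counts[["non_specific"]]
    af <- runif(k)
    rows$ns <- data.frame(category = "non_specific",
                          af_A = af, af_B = af, af_C = af,
                          rf = NA_real_, specific_pop = NA_character_,
                          stringsAsFactors = FALSE)
  }
  if (counts[["population_specific"]] > 0) {
    k <- counts[["population_specific"]]
    pop <- POPS[((seq_len(k) - 1L) %% 3L) + 1L]
    fixed <- runif(k) < 0.5
    af_carrier <- ifelse(fixed, 1, runif(k, 0.4, 1))
    af <- matrix(0, k, 3L, dimnames = list(NULL, POPS))
    af[cbind(seq_len(k), match(pop, POPS))] <- af_carrier
    rows$ps <- data.frame(category = "population_specific",
                          af_A = af[, "A"], af_B = af[, "B"], af_C = af[, "C"],
                          rf = NA_real_, specific_pop = pop,
                          stringsAsFactors = FALSE)
  }
  if (counts[["stratified"]] > 0) {
    k <- counts[["stratified"]]
    rf <- runif(k)
    af <- sapply(POPS, function(p)
      vapply(rf, function(r) balding_nichols_freq(r, fst[[p]]), numeric(1)))
    af <- matrix(af, nrow = k, dimnames = list(NULL, POPS))
    rows$st <- data.frame(category = "stratified",
                          af_A = af[, "A"], af_B = af[, "B"], af_C = af[, "C"],
                          rf = rf, specific_pop = NA_character_,
                          stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, unname(rows)) else
    data.frame(category = character(), af_A = numeric(), af_B = numeric(),
               af_C = numeric(), rf = numeric(), specific_pop = character(),
               stringsAsFactors = FALSE)
  n <- nrow(tab)
  tab <- cbind(snp_id = sprintf("snp_%05d", seq_len(n)), tab,
               stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  class(tab) <- c("af_table", "data.frame")
  tab
}

af_matrix <- function(af_table) {
  m <- as.matrix(af_table[, c("af_A", "af_B", "af_C")])
  colnames(m) <- POPS
  rownames(m) <- af_table$snp_id
  m
}

#' Sample genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each sample's dosage at each SNP is drawn independently with genotype
#' probabilities `(1 - Af)^2`, `2 Af (1 - Af)` and `Af^2` for dosages 0, 1
#' and 2, where `Af` is the alternate-allele frequency of that sample's
#' population.
#'
#' Synthetic SNP metadata places all SNPs on chromosome 1 at 1 Mb spacing
#' (so LD windows never span two simulated SNPs) with INFO fixed at 1.0 and
#' MAF computed from the realized cohort.
#'
#' @param af_table An `af_table` from [draw_allele_frequencies()].
#' @param pop_assignment Character vector, one population label per sample.
#' @param sample_ids Optional sample identifiers (default `s00001`, ...).
#' @return A `genotype_dataset`: list with integer `dosages`
#'   (samples x SNPs), `sample_ids`, `pop_labels` and `snp_meta`.
#' @export
sample_genotypes <- function(af_table, pop_assignment, sample_ids = NULL) {
  if (!inherits(af_table, "af_table") || nrow(af_table) == 0L)
    abort_validation("`af_table` must be a non-empty af_table")
  pop_assignment <- as.character(pop_assignment)
  bad <- setdiff(unique(pop_assignment), POPS)
  if (length(bad))
    abort_data(paste0("unknown population label(s): ", paste(bad, collapse = ", ")))
  m <- length(pop_assignment)
  if (m == 0L) abort_validation("at least one sample required")
  if (is.null(sample_ids)) sample_ids <- sprintf("s%05d", seq_len(m))
  af <- af_matrix(af_table)
  s <- nrow(af)
  g <- matrix(0L, m, s)
  for (p in POPS) {  # fixed population order keeps draws reproducible
    idx <- which(pop_assignment == p)
    if (!length(idx)) next
    g[idx, ] <- matrix(rbinom(length(idx) * s, 2L, rep(af[, p], each = length(idx))),
                       length(idx), s)
  }
  storage.mode(g) <- "integer"
  dimnames(g) <- list(sample_ids, af_table$snp_id)
  f <- colMeans(g) / 2
  snp_meta <- data.frame(
    id = af_table$snp_id,
    chrom = 1L,
    pos = 1e6 * seq_len(s),
    ref = "A", alt = "G",
    info = 1.0,
    maf = unname(pmin(f, 1 - f)),
    category = af_table$category,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  new_genotype_dataset(g, sample_ids, pop_assignment, snp_meta)
}

new_genotype_dataset <- function(dosages, sample_ids, pop_labels, snp_meta) {
  stopifnot(nrow(dosages) == length(sample_ids),
            ncol(dosages) == nrow(snp_meta))
  structure(list(dosages = dosages, sample_ids = sample_ids,
                 pop_labels = pop_labels, snp_meta = snp_meta),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("<genotype_dataset> ", nrow(x$dosages), " samples x ", ncol(x$dosages),
      " SNPs\n", sep = "")
  if (!is.null(x$pop_labels))
    cat("  populations:", paste(names(table(x$pop_labels)),
                                table(x$pop_labels), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Simulate a continuous phenotype at a target heritability
#'
#' Selects causal SNPs uniformly at random within each SNP category (a
#' fraction `causal_fraction` of the category, rounded), draws their effect
#' sizes from N(0, 1), and builds the genetic component `Yg = G beta`. The
#' environmental component is `Ye ~ N(0, sigma^2_Yg (1 - h2) / h2)`, where
#' `sigma^2_Yg` is the realized variance of `Yg` in this cohort, so the
#' expected narrow-sense heritability of `Y = Yg + Ye` equals `h2`.
#'
#' @param geno A `genotype_dataset`.
#' @param af_table The `af_table` the genotypes were drawn from (defines the
#'   category of each SNP for causal selection).
#' @param h2 Target heritability in (0, 1]; `h2 = 1` gives `Ye = 0`.
#' @param causal_fraction Fraction of SNPs per category that are causal.
#' @param causal Optional pre-drawn causal set, a data.frame with columns
#'   `snp_id` and `beta`; used to share one genetic architecture across
#'   cohorts. When supplied, `causal_fraction` is ignored.
#' @return A `sim_phenotype`: list with `y`, `y_genetic`, `y_env` (named by
#'   sample) and the `causal` effect table.
#' @export
simulate_phenotype <- function(geno, af_table, h2 = 0.6, causal_fraction = 0.1,
                               causal = NULL) {
  if (!is.numeric(h2) || h2 <= 0 || h2 > 1)
    abort_validation("`h2` must be in (0, 1]")
  if (is.null(causal)) {
    causal <- draw_causal_effects(af_table, causal_fraction)
  }
  if (nrow(causal) == 0L)
    abort_validation("no causal SNPs selected; increase `causal_fraction` or SNP counts")
  miss <- setdiff(causal$snp_id, colnames(geno$dosages))
  if (length(miss))
    abort_data(paste0("causal SNPs absent from genotypes: ",
                      paste(head(miss, 5), collapse = ", ")))
  gsub <- geno$dosages[, causal$snp_id, drop = FALSE]
  yg <- as.numeric(gsub %*% causal$beta)
  v <- var(yg)
  if (!is.finite(v) || v == 0)
    abort_data("degenerate genetic variance: all causal SNPs are monomorphic in this cohort")
  ye <- rnorm(length(yg), 0, sqrt(v * (1 - h2) / h2))
  y <- yg + ye
  names(y) <- names(yg) <- names(ye) <- geno$sample_ids
  structure(list(y = y, y_genetic = yg, y_env = ye, causal = causal, h2 = h2),
            class = "sim_phenotype")
}

#' Draw a causal-SNP set with Gaussian effect sizes
#'
#' @inheritParams simulate_phenotype
#' @return data.frame with `snp_id`, `category`, `beta`.
#' @export
draw_causal_effects <- function(af_table, causal_fraction = 0.1) {
  if (causal_fraction < 0 || causal_fraction > 1)
    abort_validation("`causal_fraction` must be in [0, 1]")
  picks <- lapply(SNP_CATEGORIES, function(cat) {
    ids <- af_table$snp_id[af_table$category == cat]
    k <- max(0L, round(causal_fraction * length(ids)))
    if (k == 0L) return(character())
    sort(sample(ids, k))
  })
  ids <- unlist(picks)
  data.frame(snp_id = ids,
             category = af_table$category[match(ids, af_table$snp_id)],
             beta = rnorm(length(ids)),
             stringsAsFactors = FALSE)
}

#' Scenario configuration for the three-population simulator
#'
#' Bundles SNP-category counts, cohort sizes and per-cohort population
#' compositions, heritability and Fst assignments into a validated config.
#'
#' @param snp_counts Named counts for `non_specific`, `population_specific`,
#'   `stratified` SNPs.
#' @param cohort_sizes Named sizes for the `base`, `calibration` and `target`
#'   cohorts (defaults 20000 / 7000 / 3000).
#' @param composition Named list of per-cohort population proportions over
#'   A, B, C (each summing to 1).
#' @param h2 Heritability of the simulated phenotype (default 0.6).
#' @param causal_fraction Causal fraction per SNP category (default 0.1).
#' @param fst Per-population Fst for stratified SNPs
#'   (default `c(A = 0.02, B = 0.02, C = 0.2)`).
#' @param n_replicates Default replicate count for [run_scenario()].
#' @param seed Master seed.
#' @param name Scenario label carried into results.
#' @return A `scenario_config` list.
#' @seealso [scenario_preset()] for the shipped scenario presets.
#' @export
scenario_config <- function(snp_counts = c(non_specific = 168,
                                           population_specific = 166,
                                           stratified = 166),
                            cohort_sizes = c(base = 20000, calibration = 7000,
                                             target = 3000),
                            composition = list(
                              base = c(A = 1/3, B = 1/3, C = 1/3),
                              calibration = c(A = 1/3, B = 1/3, C = 1/3),
                              target = c(A = 1/3, B = 1/3, C = 1/3)),
                            h2 = 0.6, causal_fraction = 0.1,
                            fst = c(A = 0.02, B = 0.02, C = 0.2),
                            n_replicates = 50L, seed = 42L,
                            name = "custom") {
  counts <- setNames(integer(3L), SNP_CATEGORIES)
  counts[names(snp_counts)] <- as.integer(snp_counts)
  if (any(counts < 0) || sum(counts) == 0L)
    abort_validation("SNP counts must be non-negative and sum to a positive total")
  ch <- c("base", "calibration", "target")
  if (!all(ch %in% names(cohort_sizes)))
    abort_validation("`cohort_sizes` must name base, calibration and target")
  sizes <- vapply(cohort_sizes[ch], as.integer, integer(1))
  if (any(sizes < 1L)) abort_validation("every cohort must be non-empty")
  if (!all(ch %in% names(composition)))
    abort_validation("`composition` must name base, calibration and target")
  comp <- lapply(composition[ch], function(w) {
    if (!all(POPS %in% names(w)) || any(w < 0) || abs(sum(w) - 1) > 1e-8)
      abort_validation("each composition must give non-negative A/B/C proportions summing to 1")
    w[POPS]
  })
  if (h2 <= 0 || h2 > 1) abort_validation("`h2` must be in (0, 1]")
  if (causal_fraction < 0 || causal_fraction > 1)
    abort_validation("`causal_fraction` must be in [0, 1]")
  structure(list(snp_counts = counts, cohort_sizes = sizes, composition = comp,
                 h2 = h2, causal_fraction = causal_fraction, fst = fst,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), name = name),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$name, "\n", sep = "")
  cat("  SNPs:", paste(names(x$snp_counts), x$snp_counts, sep = "=",
                       collapse = " "), "\n")
  cat("  cohorts:", paste(names(x$cohort_sizes), x$cohort_sizes, sep = "=",
                          collapse = " "), "\n")
  for (ch in names(x$composition))
    cat("   ", ch, "composition:",
        paste(POPS, round(x$composition[[ch]], 3), sep = "=", collapse = " "), "\n")
  cat("  h2 =", x$h2, " causal_fraction =", x$causal_fraction, "\n")
  invisible(x)
}

#' Shipped scenario presets
#'
#' Two preset families, all at 500 SNPs total, heritability 0.6 and base /
#' calibration / target sizes 20000 / 7000 / 3000:
#'
#' *Genetic-architecture family* (population compositions equal thirds in all
#' cohorts; the SNP category mix varies):
#' * `"architecture-control"`: 500 non-specific SNPs, no structure signal;
#' * `"architecture-specific"`: 250 non-specific + 250 population-specific;
#' * `"architecture-stratified"`: 250 non-specific + 250 stratified;
#' * `"architecture-mixed"`: 168 / 166 / 166 across the three categories.
#'
#' *Cohort-composition family* (SNP mix fixed at the mixed architecture; the
#' population composition of the cohorts varies):
#' * `"composition-homogeneous"`: equal thirds everywhere;
#' * `"composition-shifted"`: base/calibration (0.6, 0.3, 0.1),
#'   target balanced;
#' * `"composition-reversed"`: base/calibration (0.6, 0.3, 0.1),
#'   target (0.1, 0.3, 0.6);
#' * `"composition-extreme"`: population C is 3% of base/calibration but 97%
#'   of the target;
#' * `"composition-absent"`: population A present in base/calibration is
#'   absent from the target.
#'
#' @param preset Preset name (see above).
#' @param ... Overrides passed to [scenario_config()] (e.g. `seed`,
#'   `n_replicates`, or a `name` relabelling the scenario in results).
#' @return A `scenario_config`.
#' @export
scenario_preset <- function(preset, ...) {
  arch <- list(
    "architecture-control"    = c(non_specific = 500, population_specific = 0,   stratified = 0),
    "architecture-specific"   = c(non_specific = 250, population_specific = 250, stratified = 0),
    "architecture-stratified" = c(non_specific = 250, population_specific = 0,   stratified = 250),
    "architecture-mixed"      = c(non_specific = 168, population_specific = 166, stratified = 166)
  )
  even <- c(A = 1/3, B = 1/3, C = 1/3)
  comp <- list(
    "composition-homogeneous" = list(base = even, calibration = even, target = even),
    "composition-shifted"     = list(base = c(A = 0.6, B = 0.3, C = 0.1),
                                     calibration = c(A = 0.6, B = 0.3, C = 0.1),
                                     target = even),
    "composition-reversed"    = list(base = c(A = 0.6, B = 0.3, C = 0.1),
                                     calibration = c(A = 0.6, B = 0.3, C = 0.1),
                                     target = c(A = 0.1, B = 0.3, C = 0.6)),
    "composition-extreme"     = list(base = c(A = 0.485, B = 0.485, C = 0.03),
                                     calibration = c(A = 0.485, B = 0.485, C = 0.03),
                                     target = c(A = 0.015, B = 0.015, C = 0.97)),
    "composition-absent"      = list(base = even, calibration = even,
                                     target = c(A = 0, B = 0.5, C = 0.5))
  )
  extra <- list(...)
  if (!"name" %in% names(extra)) extra$name <- preset
  if (preset %in% names(arch)) {
    do.call(scenario_config, c(list(snp_counts = arch[[preset]]), extra))
  } else if (preset %in% names(comp)) {
    do.call(scenario_config, c(list(composition = comp[[preset]]), extra))
  } else {
    abort_validation(paste0("unknown preset '", preset, "'; available: ",
                            paste(c(names(arch), names(comp)), collapse = ", ")))
  }
}

#' Generate base, calibration and target cohorts for one scenario
#'
#' Draws one allele-frequency table and one causal-effect vector, shared by
#' all three cohorts, then samples genotypes and phenotypes independently per
#' cohort with the configured population composition. Identical `config` and
#' `seed` reproduce the cohorts bit for bit.
#'
#' @param config A [scenario_config()].
#' @param seed Seed overriding `config$seed` (used by [run_scenario()] to
#'   derive per-replicate seeds).
#' @return List with `base`, `calibration`, `target` (each a list of
#'   `geno` and `pheno`), plus the shared `af_table` and `causal` table.
#' @export
build_cohorts <- function(config, seed = NULL) {
  if (!inherits(config, "scenario_config"))
    abort_validation("`config` must be a scenario_config")
  set.seed(seed %||% config$seed)
  af <- draw_allele_frequencies(config$snp_counts, fst = config$fst)
  causal <- draw_causal_effects(af, config$causal_fraction)
  out <- list()
  for (ch in c("base", "calibration", "target")) {
    n <- config$cohort_sizes[[ch]]
    cnt <- allocate_counts(n, config$composition[[ch]])
    pops <- rep(POPS, cnt)
    ids <- sprintf("%s_%05d", ch, seq_len(n))
    geno <- sample_genotypes(af, pops, sample_ids = ids)
    pheno <- simulate_phenotype(geno, af, h2 = config$h2, causal = causal)
    out[[ch]] <- list(geno = geno, pheno = pheno)
  }
  out$af_table <- af
  out$causal <- causal
  out
}
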