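# Shared fixture builders. All randomness is seeded by the caller.

# Genotype dataset straight from a dosage matrix, with evenly spaced
# positions on one chromosome.
toy_geno <- function(dosages, pops = rep("A", nrow(dosages)),
                     pos = 1e6 * seq_len(ncol(dosages)),
                     info = rep(1, ncol(dosages)),
                     chrom = rep(1L, ncol(dosages))) {
  ids <- colnames(dosages) %||% sprintf("snp_%05d", seq_len(ncol(dosages)))
  colnames(dosages) <- ids
  f <- colMeans(dosages) / 2
  meta <- data.frame(id = ids, chrom = chrom, pos = pos, ref = "A", alt = "G",
                     info = info, maf = pmin(f, 1 - f),
                     stringsAsFactors = FALSE)
  ancestryscore:::new_genotype_dataset(
    dosages, rownames(dosages) %||% sprintf("s%04d", seq_len(nrow(dosages))),
    pops, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random biallelic dosage matrix with independent SNPs.
random_dosages <- function(n, s, maf_range = c(0.1, 0.5)) {
  af <- runif(s, maf_range[1], maf_range[2])
  m <- matrix(rbinom(n * s, 2L, rep(af, each = n)), n, s)
  storage.mode(m) <- "integer"
  m
}

# Small three-population cohort with clear structure, for PCA tests.
structured_geno <- function(n_per_pop = 60, s = 90, seed = 42) {
  set.seed(seed)
  af <- ancestryscore::draw_allele_frequencies(
    c(non_specific = s %/% 3, population_specific = s %/% 3,
      stratified = s - 2 * (s %/% 3)))
  ancestryscore::sample_genotypes(af, rep(c("A", "B", "C"), each = n_per_pop))
}

# Independent reference implementation of greedy LD clumping, written as the
# literal rule: walk SNPs by ascending p; an unclaimed SNP becomes an index
# and claims every unclaimed SNP within the window at r^2 >= cutoff.
clump_reference <- function(ids, chrom, pos, pvalue, dosage_mat,
                            window_kb = 250, r2_cut = 0.01) {
  ord <- order(pvalue, chrom, pos)
  claimed <- setNames(rep(FALSE, length(ids)), ids)
  index <- character()
  for (i in ord) {
    if (claimed[ids[i]]) next
    index <- c(index, ids[i])
    claimed[ids[i]] <- TRUE
    for (j in seq_along(ids)) {
      if (claimed[ids[j]]) next
      if (chrom[j] != chrom[i]) next
      if (abs(pos[j] - pos[i]) > window_kb * 1000) next
      r <- suppressWarnings(cor(dosage_mat[, i], dosage_mat[, j]))
      if (is.finite(r) && r^2 >= r2_cut) claimed[ids[j]] <- TRUE
    }
  }
  ids_sorted <- index[order(chrom[match(index, ids)], pos[match(index, ids)])]
  ids_sorted
}
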