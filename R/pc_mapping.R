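# Map-cohort PC space: reference-SNP selection, PCA loadings, projection of
# other cohorts into the shared space ("mapped PCs"), tagging-SNP fallback.

#' Select the reference SNP set shared by base and map cohorts
#'
#' Builds the reference set S1 on which the map-cohort PC space is defined:
#' base-cohort SNPs passing the imputation-quality filter (`INFO > info_min`)
#' are intersected with map-cohort SNPs passing `MAF > maf_min` that survive
#' greedy LD pruning (squared dosage correlation `r^2 <= ld_r2` within a
#' `window_kb` sliding window; of a correlated pair the SNP at the lower
#' genomic coordinate is kept). The result is ordered by map-cohort genomic
#' position.
#'
#' @param base_meta data.frame of base-cohort SNP metadata with columns `id`
#'   and `info`.
#' @param map_geno `genotype_dataset` of the map cohort.
#' @param maf_min Map-cohort minor-allele-frequency floor (default 0.01).
#' @param ld_r2 Pruning threshold on r^2 (default 0.5).
#' @param window_kb Sliding-window width in kb (default 250).
#' @param info_min Base-cohort INFO floor (default 0.9).
#' @return Character vector of SNP ids (the set S1) in genomic order.
#' @export
select_reference_snps <- function(base_meta, map_geno, maf_min = 0.01,
                                  ld_r2 = 0.5, window_kb = 250,
                                  info_min = 0.9) {
  if (!all(c("id", "info") %in% names(base_meta)))
    abort_validation("`base_meta` needs columns `id` and `info`")
  base_keep <- base_meta$id[base_meta$info > info_min]
  meta <- map_geno$snp_meta
  g <- map_geno$dosages
  f <- colMeans(g) / 2
  maf <- pmin(f, 1 - f)
  map_keep <- meta$id[maf > maf_min]
  map_keep <- prune_ld(map_geno, map_keep, ld_r2 = ld_r2, window_kb = window_kb)
  s1 <- intersect(map_keep, base_keep)
  if (!length(s1))
    abort_data("no SNPs shared between base and map cohorts after filtering; harmonize SNP ids")
  ord <- order(meta$chrom[match(s1, meta$id)], meta$pos[match(s1, meta$id)])
  s1[ord]
}

# Greedy LD pruning along genomic order: walk SNPs by (chrom, pos); a kept
# SNP removes later SNPs within window_kb whose squared dosage correlation
# exceeds ld_r2.
prune_ld <- function(geno, snp_ids, ld_r2 = 0.5, window_kb = 250) {
  meta <- geno$snp_meta
  idx <- match(snp_ids, meta$id)
  if (anyNA(idx)) abort_validation("`snp_ids` absent from genotype metadata")
  ord <- order(meta$chrom[idx], meta$pos[idx])
  idx <- idx[ord]
  chrom <- meta$chrom[idx]; pos <- meta$pos[idx]
  keep <- rep(TRUE, length(idx))
  win <- window_kb * 1000
  for (i in seq_along(idx)) {
    if (!keep[i]) next
    j <- i + 1L
    while (j <= length(idx) && chrom[j] == chrom[i] && pos[j] - pos[i] <= win) {
      if (keep[j]) {
        r <- suppressWarnings(cor(geno$dosages[, idx[i]], geno$dosages[, idx[j]]))
        if (is.finite(r) && r * r > ld_r2) keep[j] <- FALSE
      }
      j <- j + 1L
    }
  }
  meta$id[idx[keep]]
}

#' Fit the map-cohort PCA and return projection loadings
#'
#' Runs a PCA on the standardized map-cohort dosage matrix restricted to the
#' reference SNP set: each SNP column is mean-centered and divided by its
#' observed dosage standard deviation, and the top `n_pcs` eigenvectors of
#' the resulting correlation matrix give the SNP loadings. The centering and
#' scaling vectors are stored with the loadings so any other cohort can be
#' projected into the same space with no access to the map genotypes.
#'
#' The sign of each PC is fixed by requiring its largest-magnitude loading to
#' be positive, making results reproducible across runs and platforms.
#'
#' @param map_geno `genotype_dataset` of the map cohort.
#' @param snp_set Reference SNP ids (S1), e.g. from
#'   [select_reference_snps()]. Default: all SNPs in `map_geno`.
#' @param n_pcs Number of PCs to retain (40 is typical for biobank-scale
#'   data; 2 suffices to separate three simulated populations).
#' @return A `map_loadings` object: `snp_ids`, `loadings` (`n_pcs` x s1),
#'   `center`, `scale`, `n_pcs`, `explained_variance`.
#' @export
fit_map_pca <- function(map_geno, snp_set = map_geno$snp_meta$id, n_pcs = 2L) {
  idx <- match(snp_set, map_geno$snp_meta$id)
  if (anyNA(idx))
    abort_validation(paste0("SNPs absent from map cohort: ",
                            paste(head(snp_set[is.na(idx)], 5), collapse = ", ")))
  g <- map_geno$dosages[, idx, drop = FALSE]
  n <- nrow(g); s1 <- ncol(g)
  if (n_pcs < 1L || n_pcs > min(n - 1L, s1))
    abort_validation(sprintf("`n_pcs` must be between 1 and min(n - 1, s1) = %d",
                             min(n - 1L, s1)))
  ctr <- colMeans(g)
  scl <- col_sds(g)
  if (any(scl == 0))
    abort_data(paste0("zero-variance SNP(s) in reference set: ",
                      paste(head(snp_set[scl == 0], 5), collapse = ", ")))
  # Correlation matrix without materializing the standardized matrix:
  # C = D^-1 (G'G - n c c') D^-1 / (n - 1)
  cc <- (crossprod(g) - n * tcrossprod(ctr)) / (n - 1)
  cc <- cc / tcrossprod(scl)
  ev <- eigen(cc, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  v <- ev$vectors[, seq_len(n_pcs), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each PC is positive
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  structure(list(snp_ids = snp_set,
                 loadings = t(v),
                 center = setNames(ctr, snp_set),
                 scale = setNames(scl, snp_set),
                 n_pcs = as.integer(n_pcs),
                 explained_variance = lam[seq_len(n_pcs)] / sum(lam)),
            class = "map_loadings")
}

#' @export
print.map_loadings <- function(x, ...) {
  cat("<map_loadings> ", x$n_pcs, " PCs on ", length(x$snp_ids),
      " reference SNPs\n", sep = "")
  cat("  explained variance:",
      paste(sprintf("%.3f", x$explained_variance), collapse = " "), "\n")
  invisible(x)
}

#' Project a cohort into the map-cohort PC space
#'
#' Computes mapped PCs: the cohort's dosages at the reference SNPs are
#' standardized with the *map-cohort* center and scale stored in the
#' loadings, then multiplied by the transposed loadings. Projecting the map
#' cohort itself recovers its native PC scores.
#'
#' @param geno `genotype_dataset` to project.
#' @param loadings A `map_loadings` from [fit_map_pca()].
#' @param source Provenance tag for the scores, `"projected"` (default) or
#'   `"native"`.
#' @return A `mapped_pcs` object: `sample_ids`, `scores` (samples x p),
#'   `source`.
#' @export
project_mapped_pcs <- function(geno, loadings, source = c("projected", "native")) {
  source <- match.arg(source)
  idx <- match(loadings$snp_ids, geno$snp_meta$id)
  if (anyNA(idx))
    abort_data(paste0("cohort is missing reference SNPs: ",
                      paste(head(loadings$snp_ids[is.na(idx)], 10), collapse = ", "),
                      "; substitute tagging SNPs or drop them from the loadings"))
  g <- geno$dosages[, idx, drop = FALSE]
  # (G - 1 c') D^-1 V  ==  G (D^-1 V) - 1 (c' D^-1 V), avoiding a dense
  # standardized copy of G
  w <- t(loadings$loadings) / loadings$scale        # s1 x p
  offs <- as.numeric(crossprod(loadings$center, w)) # length p
  scores <- g %*% w
  scores <- sweep(scores, 2L, offs, "-")
  colnames(scores) <- paste0("PC", seq_len(loadings$n_pcs))
  rownames(scores) <- geno$sample_ids
  structure(list(sample_ids = geno$sample_ids, scores = scores, source = source),
            class = "mapped_pcs")
}

#' @export
print.mapped_pcs <- function(x, ...) {
  cat("<mapped_pcs> ", nrow(x$scores), " samples x ", ncol(x$scores),
      " PCs (", x$source, ")\n", sep = "")
  invisible(x)
}

#' Substitute missing reference SNPs with their best tagging SNPs
#'
#' For each required SNP absent from a target cohort, searches the map-cohort
#' LD window around it and picks the available SNP maximizing
#' `INFO x r^2` (imputation quality times squared dosage correlation in the
#' map cohort). SNPs with no candidate scoring above `min_score` are
#' reported as dropped rather than raising an error.
#'
#' @param required Reference SNP ids needed (e.g. loadings `snp_ids`).
#' @param available SNP ids present in the target cohort.
#' @param ld_reference `genotype_dataset` (map cohort) providing positions
#'   and dosages for the r^2 computation.
#' @param info Named per-SNP INFO scores; defaults to the `info` column of
#'   the LD reference metadata.
#' @param window_kb Search window in kb (default 250).
#' @param min_score Floor on `INFO x r^2` below which no substitution is made.
#' @return List with `substitutions` (named character vector,
#'   missing SNP -> tagging SNP) and `dropped` (character vector).
#' @export
substitute_tagging_snps <- function(required, available, ld_reference,
                                    info = NULL, window_kb = 250,
                                    min_score = 0) {
  meta <- ld_reference$snp_meta
  if (is.null(info)) info <- setNames(meta$info, meta$id)
  missing <- setdiff(required, available)
  if (!length(missing))
    return(list(substitutions = setNames(character(), character()),
                dropped = character()))
  subs <- character(); dropped <- character()
  win <- window_kb * 1000
  for (snp in missing) {
    i <- match(snp, meta$id)
    if (is.na(i)) { dropped <- c(dropped, snp); next }
    cand <- which(meta$chrom == meta$chrom[i] &
                    abs(meta$pos - meta$pos[i]) <= win &
                    meta$id %in% available)
    if (!length(cand)) { dropped <- c(dropped, snp); next }
    r <- suppressWarnings(
      as.numeric(cor(ld_reference$dosages[, i],
                     ld_reference$dosages[, cand, drop = FALSE])))
    score <- info[meta$id[cand]] * r * r
    score[!is.finite(score)] <- -Inf
    best <- which.max(score)
    if (score[best] > min_score) {
      subs[snp] <- meta$id[cand[best]]
    } else {
      dropped <- c(dropped, snp)
    }
  }
  if (length(dropped))
    message("tagging substitution dropped ", length(dropped),
            " SNP(s) with no usable candidate")
  list(substitutions = subs, dropped = dropped)
}
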