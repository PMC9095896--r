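# PGS construction (clumping + p-value thresholding) and score computation
# (PGS from GWAS weights, AS from PCAS weights).

#' Default p-value threshold grid for PGS optimization
#'
#' @return Ascending numeric vector of candidate thresholds.
#' @export
pgs_threshold_grid <- function() {
  c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1)
}

#' Greedy LD clumping of GWAS results
#'
#' Iterates SNPs by ascending GWAS p-value; each SNP not yet claimed by a
#' clump becomes an index SNP and claims every unclaimed SNP within
#' `window_kb` whose squared dosage correlation with it (in the LD
#' reference) is at least `r2_cut`. The index SNPs - one per clump, each the
#' smallest-p member - are returned in genomic order.
#'
#' @param gwas `summary_stats` of kind `"gwas"`.
#' @param ld_reference `genotype_dataset` supplying dosages for the r^2
#'   computation (a reference panel or the target cohort).
#' @param window_kb Maximum clump radius in kb (default 250).
#' @param r2_cut r^2 at or above which a SNP joins the index SNP's clump
#'   (default 0.01).
#' @param p_max Only SNPs with p <= `p_max` participate (default 1).
#' @return Character vector of index SNP ids.
#' @export
clump_snps <- function(gwas, ld_reference, window_kb = 250, r2_cut = 0.01,
                       p_max = 1) {
  if (!identical(attr(gwas, "kind"), "gwas"))
    abort_validation("`gwas` must be summary_stats of kind 'gwas'")
  keep <- gwas$tested & !is.na(gwas$pvalue) & gwas$pvalue <= p_max
  snps <- gwas[keep, , drop = FALSE]
  in_ref <- snps$id %in% ld_reference$snp_meta$id
  if (any(!in_ref)) {
    warning(sum(!in_ref), " GWAS SNP(s) absent from the LD reference; excluded")
    snps <- snps[in_ref, , drop = FALSE]
  }
  if (nrow(snps) == 0L) return(character())
  ord <- order(snps$pvalue, snps$chrom, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  ref_idx <- match(snps$id, ld_reference$snp_meta$id)
  claimed <- rep(FALSE, nrow(snps))
  index <- logical(nrow(snps))
  win <- window_kb * 1000
  for (i in seq_len(nrow(snps))) {
    if (claimed[i]) next
    index[i] <- TRUE
    cand <- which(!claimed & snps$chrom == snps$chrom[i] &
                    abs(snps$pos - snps$pos[i]) <= win)
    cand <- setdiff(cand, i)
    if (length(cand)) {
      r <- suppressWarnings(
        as.numeric(cor(ld_reference$dosages[, ref_idx[i]],
                       ld_reference$dosages[, ref_idx[cand], drop = FALSE])))
      hit <- is.finite(r) & r * r >= r2_cut
      claimed[cand[hit]] <- TRUE
    }
    claimed[i] <- TRUE
  }
  out <- snps[index, , drop = FALSE]
  out$id[order(out$chrom, out$pos)]
}

#' Optimize the PGS p-value threshold on a calibration cohort
#'
#' For each candidate threshold, builds a PGS from the clumped SNPs with
#' GWAS p-value at or below the threshold, scores the calibration cohort,
#' and records the coefficient of determination of the calibration phenotype
#' regressed on that PGS. The threshold maximizing the calibration R^2 wins;
#' ties break toward the smaller threshold (the sparser score). Thresholds
#' admitting no SNP are recorded with R^2 = 0 and skipped for selection.
#'
#' @param gwas `summary_stats` of kind `"gwas"`.
#' @param clumped SNP ids surviving [clump_snps()] (for simulated
#'   independent SNPs, simply all tested SNPs).
#' @param calib_geno Calibration-cohort `genotype_dataset`.
#' @param calib_pheno Calibration phenotype (vector or `sim_phenotype`).
#' @param thresholds Candidate thresholds in (0, 1]; default
#'   [pgs_threshold_grid()].
#' @return A `pgs_formula`: selected SNP ids, effect alleles, weights, the
#'   winning `p_threshold`, and `calibration_r2_by_threshold`.
#' @export
optimize_pgs_threshold <- function(gwas, clumped, calib_geno, calib_pheno,
                                   thresholds = pgs_threshold_grid()) {
  if (!length(clumped)) abort_validation("`clumped` SNP set is empty")
  if (!length(thresholds) || any(thresholds <= 0 | thresholds > 1))
    abort_validation("`thresholds` must be non-empty values in (0, 1]")
  thresholds <- sort(unique(thresholds))
  if (inherits(calib_pheno, "sim_phenotype")) calib_pheno <- calib_pheno$y
  y <- as.numeric(calib_pheno)
  rows <- gwas[match(clumped, gwas$id), , drop = FALSE]
  rows <- rows[rows$tested & !is.na(rows$pvalue), , drop = FALSE]
  if (nrow(rows) == 0L) abort_data("no clumped SNP has a usable GWAS estimate")
  gidx <- match(rows$id, calib_geno$snp_meta$id)
  if (anyNA(gidx))
    abort_data(paste0("clumped SNPs missing from calibration genotypes: ",
                      paste(head(rows$id[is.na(gidx)], 5), collapse = ", ")))
  g <- calib_geno$dosages[, gidx, drop = FALSE]
  storage.mode(g) <- "double"
  r2 <- setNames(numeric(length(thresholds)), format(thresholds))
  for (k in seq_along(thresholds)) {
    sel <- rows$pvalue <= thresholds[k]
    if (!any(sel)) { r2[k] <- 0; next }
    pgs <- g[, sel, drop = FALSE] %*% rows$beta[sel]
    r <- suppressWarnings(cor(y, pgs))
    r2[k] <- if (is.finite(r)) r * r else 0
  }
  admits <- vapply(thresholds, function(t) any(rows$pvalue <= t), logical(1))
  if (!any(admits)) abort_data("no threshold admits any SNP")
  cand <- which(admits)
  best <- cand[which.max(r2[cand])]
  sel <- rows$pvalue <= thresholds[best]
  structure(list(snp_ids = rows$id[sel],
                 effect_alleles = rows$alt[sel],
                 weights = setNames(rows$beta[sel], rows$id[sel]),
                 p_threshold = thresholds[best],
                 clump_window_kb = NA_real_, clump_r2 = NA_real_,
                 calibration_r2_by_threshold = r2),
            class = "pgs_formula")
}

#' @export
print.pgs_formula <- function(x, ...) {
  cat("<pgs_formula> ", length(x$snp_ids), " SNPs at p <= ",
      format(x$p_threshold), "\n", sep = "")
  cat("  calibration R2 by threshold:\n")
  print(round(x$calibration_r2_by_threshold, 4))
  invisible(x)
}

#' Compute polygenic scores
#'
#' Per-sample weighted sum of alternate-allele dosages over the SNPs of a
#' PGS formula. Up to 5% of formula SNPs may be missing from the cohort (a
#' warning is raised and their contribution treated as dosage 0); more is an
#' error - substitute tagging SNPs first.
#'
#' @param geno `genotype_dataset` to score.
#' @param formula A `pgs_formula`.
#' @return A `score_vector` data.frame (`sample_id`, `value`) of kind
#'   `"pgs"`.
#' @export
compute_pgs <- function(geno, formula) {
  ids <- formula$snp_ids
  idx <- match(ids, geno$snp_meta$id)
  miss <- is.na(idx)
  if (mean(miss) > 0.05)
    abort_data(sprintf("%.1f%% of PGS SNPs missing from cohort (max 5%%)",
                       100 * mean(miss)))
  if (any(miss))
    warning(sum(miss), " PGS SNP(s) missing from cohort; scored as dosage 0")
  g <- geno$dosages[, idx[!miss], drop = FALSE]
  storage.mode(g) <- "double"
  val <- as.numeric(g %*% formula$weights[!miss])
  new_score_vector(geno$sample_ids, val, kind = "pgs")
}

#' Compute ancestry scores
#'
#' Per-sample dot product of mapped-PC coordinates with the PCAS effect
#' sizes: the ancestry score is the phenotype component predictable from
#' position in the shared ancestry space.
#'
#' @param pcs `mapped_pcs` of the cohort to score.
#' @param pcas `summary_stats` of kind `"pcas"`.
#' @return A `score_vector` of kind `"as"`.
#' @export
compute_as <- function(pcs, pcas) {
  if (!identical(attr(pcas, "kind"), "pcas"))
    abort_validation("`pcas` must be summary_stats of kind 'pcas'")
  p <- nrow(pcas)
  if (ncol(pcs$scores) < p)
    abort_validation(sprintf("mapped PCs have %d columns but PCAS tested %d PCs",
                             ncol(pcs$scores), p))
  val <- as.numeric(pcs$scores[, seq_len(p), drop = FALSE] %*% pcas$beta)
  new_score_vector(pcs$sample_ids, val, kind = "as")
}

score_values <- function(x) {
  if (inherits(x, "score_vector")) x$value else as.numeric(x)
}

new_score_vector <- function(sample_ids, value, kind) {
  structure(data.frame(sample_id = sample_ids, value = value,
                       stringsAsFactors = FALSE),
            kind = kind, class = c("score_vector", "data.frame"))
}

#' @export
print.score_vector <- function(x, ...) {
  cat("<score_vector> kind =", attr(x, "kind"), "|", nrow(x), "samples\n")
  NextMethod()
}
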