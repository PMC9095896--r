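# Association scans on the base cohort: per-SNP GWAS and the joint
# principal-component association study (PCAS).

#' Per-SNP association scan (GWAS)
#'
#' Fits, for every SNP passing the MAF / INFO filters, the ordinary
#' least-squares model `y ~ dosage + covariates + intercept` and reports the
#' dosage coefficient with its standard error and two-sided p-value from the
#' t distribution on `n - k - 1` degrees of freedom. Computation uses
#' Frisch-Waugh-Lovell residualization (y and every dosage column are
#' projected off the covariate space once), which is algebraically identical
#' to the full per-SNP regression but runs vectorized across SNPs.
#'
#' Zero-variance SNPs, and SNPs whose dosages are (numerically) collinear
#' with the covariates, are emitted with `NA` estimates and a note instead
#' of being dropped, so output rows stay aligned with the input metadata.
#'
#' @param geno `genotype_dataset` of the base cohort.
#' @param y Phenotype: numeric vector or a `sim_phenotype`.
#' @param covariates Optional numeric matrix of covariates (e.g. the first
#'   mapped PCs); must be full rank together with the intercept.
#' @param maf_min,info_min Filters on SNP metadata; defaults 0 (no
#'   filtering, the simulation-mode convention). Typical observational-data
#'   settings are `maf_min = 1e-4`, `info_min = 0.8`.
#' @param vif_max Collinearity guard: a SNP whose dosage is almost fully
#'   explained by the covariates (variance-inflation factor above
#'   `vif_max`, i.e. residual variance share below `1 / vif_max`) gets `NA`
#'   estimates and the note `"collinear_with_covariates"`. This mirrors the
#'   multicollinearity check of standard GWAS software and is what
#'   nullifies population-specific variants when ancestry PCs are included
#'   as covariates. Default 50.
#' @return A `summary_stats` data.frame (kind `"gwas"`) with columns `id`,
#'   `chrom`, `pos`, `ref`, `alt`, `beta`, `se`, `pvalue`, `n`, `tested`,
#'   `note`.
#' @export
run_gwas <- function(geno, y, covariates = NULL, maf_min = 0, info_min = 0,
                     vif_max = 50) {
  if (inherits(y, "sim_phenotype")) y <- y$y
  y <- as.numeric(y)
  g <- geno$dosages
  n <- nrow(g)
  if (length(y) != n) abort_validation("`y` length must match sample count")
  q <- covariate_basis(covariates, n)
  k <- ncol(q)                     # intercept + covariates
  yr <- as.numeric(y - q %*% crossprod(q, y))
  meta <- geno$snp_meta
  pass <- (meta$maf > maf_min | maf_min <= 0) & meta$info >= info_min
  beta <- se <- pval <- rep(NA_real_, ncol(g))
  note <- rep(NA_character_, ncol(g))
  note[!pass] <- "filtered"
  idx <- which(pass)
  if (length(idx)) {
    gs <- g[, idx, drop = FALSE]
    storage.mode(gs) <- "double"
    raw_ss <- colSums(gs * gs) - n * colMeans(gs)^2
    gr <- gs - q %*% crossprod(q, gs)
    s2g <- colSums(gr * gr)
    zerovar <- raw_ss <= 0
    collin <- !zerovar & s2g <= raw_ss / vif_max
    ok <- !zerovar & !collin
    df <- n - k - 1L
    if (df < 1L) abort_validation("not enough samples for the covariate count")
    b <- rep(NA_real_, length(idx))
    b[ok] <- colSums(gr[, ok, drop = FALSE] * yr) / s2g[ok]
    rss <- sum(yr * yr) - b^2 * s2g
    sez <- sqrt(pmax(rss, 0) / df / s2g)
    pv <- 2 * pt(-abs(b / sez), df)
    beta[idx] <- b
    se[idx][ok] <- sez[ok]
    pval[idx][ok] <- pv[ok]
    note[idx][zerovar] <- "zero_variance"
    note[idx][collin] <- "collinear_with_covariates"
  }
  out <- data.frame(id = meta$id, chrom = meta$chrom, pos = meta$pos,
                    ref = meta$ref, alt = meta$alt,
                    beta = beta, se = se, pvalue = pval, n = n,
                    tested = pass & !is.na(beta) & !is.na(se),
                    note = note, stringsAsFactors = FALSE)
  new_summary_stats(out, kind = "gwas",
                    covariate_names = colnames(covariates) %||% character())
}

#' Principal-component association study (PCAS)
#'
#' Fits one joint multiple linear regression of the phenotype on the first
#' `n_pcs` mapped PCs (plus optional covariates and an intercept) and
#' returns the per-PC effect sizes with standard errors and t-test p-values.
#' These "PCAS summary statistics" are the weights of the ancestry score.
#'
#' @param pcs A `mapped_pcs` object (or a bare score matrix).
#' @param y Phenotype: numeric vector or `sim_phenotype`.
#' @param covariates Optional covariate matrix (non-PC covariates only).
#' @param n_pcs Number of leading PCs to test jointly (default: all).
#' @return A `summary_stats` data.frame (kind `"pcas"`) with one row per PC:
#'   `id` (`PC1`, ...), `beta`, `se`, `pvalue`, `n`.
#' @export
run_pcas <- function(pcs, y, covariates = NULL, n_pcs = NULL) {
  scores <- if (inherits(pcs, "mapped_pcs")) pcs$scores else as.matrix(pcs)
  if (inherits(y, "sim_phenotype")) y <- y$y
  y <- as.numeric(y)
  n <- nrow(scores)
  if (length(y) != n) abort_validation("`y` length must match sample count")
  p <- n_pcs %||% ncol(scores)
  if (p > ncol(scores))
    abort_validation(sprintf("`n_pcs` = %d exceeds the %d available PCs", p, ncol(scores)))
  x <- cbind(`(Intercept)` = 1, scores[, seq_len(p), drop = FALSE])
  if (!is.null(covariates)) x <- cbind(x, as.matrix(covariates))
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    drop_cols <- colnames(x)[qrx$pivot[(qrx$rank + 1L):ncol(x)]]
    abort_data(paste0("design matrix is rank deficient; collinear column(s): ",
                      paste(drop_cols, collapse = ", ")))
  }
  bhat <- qr.coef(qrx, y)
  res <- y - x %*% bhat
  df <- n - ncol(x)
  sigma2 <- sum(res * res) / df
  xtx_inv <- chol2inv(chol(crossprod(x)))
  se <- sqrt(sigma2 * diag(xtx_inv))
  keep <- seq_len(p) + 1L   # PC rows only (skip intercept, covariates)
  tt <- bhat[keep] / se[keep]
  out <- data.frame(id = paste0("PC", seq_len(p)),
                    beta = unname(bhat[keep]), se = unname(se[keep]),
                    pvalue = unname(2 * pt(-abs(tt), df)), n = n,
                    tested = TRUE, note = NA_character_,
                    stringsAsFactors = FALSE)
  new_summary_stats(out, kind = "pcas",
                    covariate_names = colnames(covariates) %||% character())
}

new_summary_stats <- function(df, kind, covariate_names = character()) {
  structure(df, kind = kind, covariate_names = covariate_names,
            class = c("summary_stats", "data.frame"))
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("<summary_stats> kind =", attr(x, "kind"), "|", nrow(x), "predictors,",
      sum(x$tested, na.rm = TRUE), "tested\n")
  NextMethod()
}

# Orthonormal basis of [1, C]; errors (naming columns) if rank deficient.
covariate_basis <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1 / sqrt(n), n, 1L))
  cmat <- as.matrix(covariates)
  if (nrow(cmat) != n) abort_validation("covariate rows must match sample count")
  if (is.null(colnames(cmat))) colnames(cmat) <- paste0("covar", seq_len(ncol(cmat)))
  x <- cbind(`(Intercept)` = 1, cmat)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1L):ncol(x)]]
    abort_data(paste0("covariates are rank deficient; collinear column(s): ",
                      paste(bad, collapse = ", ")))
  }
  qr.Q(qrx)
}
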