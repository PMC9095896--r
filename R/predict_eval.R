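# Predictive-model calibration, phenotype prediction, PVE/MSE evaluation,
# and the end-to-end simulation scenario driver.

#' Calibrate the predictive model on the calibration cohort
#'
#' Ordinary least-squares fit of the calibration phenotype on the PGS,
#' optionally the ancestry score, and optional covariates (plus an
#' intercept). This is the model whose coefficients are later applied to
#' target-cohort scores.
#'
#' @param pgs `score_vector` (or numeric vector) of polygenic scores.
#' @param as_score Optional `score_vector` (or numeric vector) of ancestry
#'   scores; required when `include_as = TRUE`.
#' @param covariates Optional covariate matrix.
#' @param y Phenotype (vector or `sim_phenotype`).
#' @param include_as Whether the model carries an AS term (default: an AS
#'   was supplied).
#' @return A `predictive_model` with `intercept`, `beta_pgs`, `beta_as`,
#'   `gamma` and `include_as`.
#' @export
calibrate_model <- function(pgs, as_score = NULL, covariates = NULL, y,
                            include_as = !is.null(as_score)) {
  pgs <- score_values(pgs)
  if (include_as && is.null(as_score))
    abort_validation("`include_as = TRUE` but no ancestry score supplied")
  if (inherits(y, "sim_phenotype")) y <- y$y
  y <- as.numeric(y)
  n <- length(y)
  if (length(pgs) != n) abort_validation("PGS length must match phenotype length")
  if (sd(pgs) == 0) abort_data("PGS is constant; cannot calibrate")
  x <- cbind(`(Intercept)` = 1, PGS = pgs)
  if (include_as) {
    asv <- score_values(as_score)
    if (length(asv) != n) abort_validation("AS length must match phenotype length")
    x <- cbind(x, AS = asv)
  }
  cov_names <- character()
  if (!is.null(covariates)) {
    cmat <- as.matrix(covariates)
    if (is.null(colnames(cmat))) colnames(cmat) <- paste0("covar", seq_len(ncol(cmat)))
    cov_names <- colnames(cmat)
    x <- cbind(x, cmat)
  }
  if (n < ncol(x) + 10L)
    abort_validation("need at least 10 samples more than model parameters")
  qrx <- qr(x)
  if (qrx$rank < ncol(x))
    abort_data("calibration design matrix is rank deficient")
  bhat <- qr.coef(qrx, y)
  structure(list(intercept = unname(bhat["(Intercept)"]),
                 beta_pgs = unname(bhat["PGS"]),
                 beta_as = if (include_as) unname(bhat["AS"]) else NULL,
                 gamma = if (length(cov_names)) bhat[cov_names] else NULL,
                 include_as = include_as,
                 covariate_names = cov_names,
                 n = n),
            class = "predictive_model")
}

#' @export
print.predictive_model <- function(x, ...) {
  cat("<predictive_model>", if (x$include_as) "PGS + AS" else "PGS only",
      "| n =", x$n, "\n")
  cat("  intercept =", signif(x$intercept, 4),
      " beta_PGS =", signif(x$beta_pgs, 4))
  if (x$include_as) cat("  beta_AS =", signif(x$beta_as, 4))
  cat("\n")
  if (length(x$covariate_names))
    cat("  covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  invisible(x)
}

#' Predict phenotypes from a calibrated model
#'
#' Applies the fitted coefficients:
#' `yhat = intercept + beta_PGS * PGS (+ beta_AS * AS) (+ gamma * C)`.
#'
#' @param model A `predictive_model`.
#' @param pgs Polygenic scores of the cohort to predict.
#' @param as_score Ancestry scores; required iff the model includes an AS
#'   term.
#' @param covariates Covariates matching the model's covariate names.
#' @return Numeric vector of predictions.
#' @export
predict_phenotype <- function(model, pgs, as_score = NULL, covariates = NULL) {
  pgs <- score_values(pgs)
  yhat <- model$intercept + model$beta_pgs * pgs
  if (model$include_as) {
    if (is.null(as_score))
      abort_validation("model includes an AS term but no ancestry score supplied")
    asv <- score_values(as_score)
    if (length(asv) != length(pgs))
      abort_validation("AS length must match PGS length")
    yhat <- yhat + model$beta_as * asv
  } else if (!is.null(as_score)) {
    abort_validation("model has no AS term but an ancestry score was supplied")
  }
  if (length(model$covariate_names)) {
    if (is.null(covariates))
      abort_validation("model includes covariates but none supplied")
    cmat <- as.matrix(covariates)
    if (!all(model$covariate_names %in% colnames(cmat)))
      abort_validation("covariates do not match the fitted model")
    yhat <- yhat + as.numeric(cmat[, model$covariate_names, drop = FALSE] %*% model$gamma)
  }
  as.numeric(yhat)
}

#' Evaluate predictions by PVE and MSE
#'
#' The phenotypic variance explained (PVE) is the coefficient of
#' determination `1 - SS_res / SS_tot` of the predictions against the
#' observed phenotypes - not a squared correlation, so systematic shifts
#' (e.g. a miscalibrated intercept on a shifted target cohort) are penalized.
#'
#' @param pred Numeric predictions.
#' @param y Observed phenotypes.
#' @return List with `pve` and `mse`.
#' @export
evaluate_predictions <- function(pred, y) {
  if (inherits(y, "sim_phenotype")) y <- y$y
  y <- as.numeric(y); pred <- as.numeric(pred)
  if (length(pred) != length(y) || length(y) < 2L)
    abort_validation("`pred` and `y` must have equal length >= 2")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) abort_data("phenotype has zero variance")
  res <- y - pred
  list(pve = 1 - sum(res * res) / ss_tot, mse = mean(res * res))
}

#' Run one full simulation scenario
#'
#' Per replicate: generate base / calibration / target cohorts
#' ([build_cohorts()]); fit the PC space on the base cohort itself (in
#' simulation the base cohort doubles as the map cohort) restricted to its
#' polymorphic SNPs; project all cohorts to mapped PCs; run the GWAS with
#' the first two PCs as covariates and the PCAS on the first `n_pcs` PCs;
#' choose the PGS p-value threshold on the calibration cohort (clumping is
#' skipped: simulated SNPs are independent); compute PGS and AS for
#' calibration and target; calibrate a PGS-only and a PGS+AS model on the
#' calibration cohort; predict and evaluate both on the target.
#'
#' @param config A [scenario_config()] or preset name for
#'   [scenario_preset()].
#' @param n_replicates Number of replicates (default from config).
#' @param seed Master seed (default from config); per-replicate seeds are
#'   derived from it deterministically.
#' @param n_pcs Number of mapped PCs (default 2, enough to separate three
#'   populations).
#' @param thresholds PGS threshold grid (default [pgs_threshold_grid()]).
#' @param progress Print one line per replicate.
#' @return data.frame with one row per replicate: `scenario_id`,
#'   `replicate`, `pve_pgs`, `pve_pgs_as`, `mse_pgs`, `mse_pgs_as`,
#'   `beta_as`, `p_threshold`, `n_target`.
#' @export
run_scenario <- function(config, n_replicates = NULL, seed = NULL,
                         n_pcs = 2L, thresholds = pgs_threshold_grid(),
                         progress = FALSE) {
  if (is.character(config)) config <- scenario_preset(config)
  if (!inherits(config, "scenario_config"))
    abort_validation("`config` must be a scenario_config or preset name")
  n_rep <- as.integer(n_replicates %||% config$n_replicates)
  if (n_rep < 1L) abort_validation("need at least one replicate")
  seeds <- derive_seeds(seed %||% config$seed, n_rep)
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    rows[[r]] <- tryCatch(
      run_replicate(config, seeds[r], n_pcs, thresholds),
      error = function(e)
        stop("replicate ", r, " failed: ", conditionMessage(e), call. = FALSE))
    rows[[r]]$replicate <- r
    if (progress)
      message(sprintf("replicate %d/%d: PVE %.3f (PGS) %.3f (PGS+AS)",
                      r, n_rep, rows[[r]]$pve_pgs, rows[[r]]$pve_pgs_as))
  }
  out <- do.call(rbind, rows)
  out$scenario_id <- config$name
  out[, c("scenario_id", "replicate", "pve_pgs", "pve_pgs_as",
          "mse_pgs", "mse_pgs_as", "beta_as", "p_threshold", "n_target")]
}

run_replicate <- function(config, seed, n_pcs, thresholds) {
  cohorts <- build_cohorts(config, seed = seed)
  base <- cohorts$base; calib <- cohorts$calibration; targ <- cohorts$target
  poly <- base$geno$snp_meta$id[col_sds(base$geno$dosages) > 0]
  loadings <- fit_map_pca(base$geno, snp_set = poly, n_pcs = n_pcs)
  pcs_base <- project_mapped_pcs(base$geno, loadings, source = "native")
  pcs_calib <- project_mapped_pcs(calib$geno, loadings)
  pcs_targ <- project_mapped_pcs(targ$geno, loadings)

  gwas <- run_gwas(base$geno, base$pheno,
                   covariates = pcs_base$scores[, 1:2, drop = FALSE])
  pcas <- run_pcas(pcs_base, base$pheno, n_pcs = n_pcs)

  formula <- optimize_pgs_threshold(gwas, clumped = gwas$id[gwas$tested],
                                    calib$geno, calib$pheno,
                                    thresholds = thresholds)
  pgs_calib <- compute_pgs(calib$geno, formula)
  pgs_targ <- compute_pgs(targ$geno, formula)
  as_calib <- compute_as(pcs_calib, pcas)
  as_targ <- compute_as(pcs_targ, pcas)

  m_pgs <- calibrate_model(pgs_calib, y = calib$pheno, include_as = FALSE)
  m_both <- calibrate_model(pgs_calib, as_calib, y = calib$pheno,
                            include_as = TRUE)
  ev1 <- evaluate_predictions(predict_phenotype(m_pgs, pgs_targ), targ$pheno)
  ev2 <- evaluate_predictions(
    predict_phenotype(m_both, pgs_targ, as_targ), targ$pheno)
  data.frame(pve_pgs = ev1$pve, pve_pgs_as = ev2$pve,
             mse_pgs = ev1$mse, mse_pgs_as = ev2$mse,
             beta_as = m_both$beta_as,
             p_threshold = formula$p_threshold,
             n_target = length(targ$pheno$y))
}

#' Summarize replicate results per scenario
#'
#' Per scenario and metric: mean, variance, and the empirical 95% replicate
#' interval (2.5th to 97.5th percentiles).
#'
#' @param results data.frame from [run_scenario()] (rows from several
#'   scenarios may be concatenated).
#' @return Long data.frame: `scenario_id`, `metric`, `mean`, `var`,
#'   `q2.5`, `q97.5`, `n_replicates`.
#' @export
summarize_results <- function(results) {
  metrics <- intersect(c("pve_pgs", "pve_pgs_as", "mse_pgs", "mse_pgs_as"),
                       names(results))
  if (nrow(results) < 2L) abort_validation("need at least 2 replicates")
  out <- list()
  for (sc in unique(results$scenario_id)) {
    sub <- results[results$scenario_id == sc, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      out[[length(out) + 1L]] <- data.frame(
        scenario_id = sc, metric = m, mean = mean(v), var = var(v),
        q2.5 = unname(quantile(v, 0.025, type = 7)),
        q97.5 = unname(quantile(v, 0.975, type = 7)),
        n_replicates = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Bar plot of PVE by model across scenarios
#'
#' Mirrors the standard presentation of simulation results: one bar per
#' scenario and model (PGS only vs PGS + AS), error bars spanning 95% of
#' replicates. Requires ggplot2.
#'
#' @param results data.frame from [run_scenario()].
#' @return A ggplot object.
#' @export
plot_scenario_summary <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    abort_validation("ggplot2 is required for plotting")
  sm <- summarize_results(results)
  sm <- sm[sm$metric %in% c("pve_pgs", "pve_pgs_as"), , drop = FALSE]
  sm$model <- ifelse(sm$metric == "pve_pgs", "PGS only", "PGS + AS")
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$scenario_id, y = .data$mean,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "Phenotypic variance explained",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
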