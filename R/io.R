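# Readers and writers for the on-disk artifacts. Primary dialect:
# tab-delimited UTF-8 with `#key: value` header metadata lines. VCF is
# supported read-only for genotypes (via vcfR). Coordinates are 1-based.

write_tsv_meta <- function(df, path, meta = list()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("#%s: %s", k, paste(meta[[k]], collapse = "\t")), con)
  close(con); on.exit()
  # doubles at full (round-trippable) precision
  is_dbl <- vapply(df, is.double, logical(1))
  df[is_dbl] <- lapply(df[is_dbl], function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- NA_character_
    out
  })
  data.table::fwrite(df, path, sep = "\t", append = length(meta) > 0,
                     col.names = TRUE, quote = FALSE)
}

meta_number <- function(x) {
  if (is.null(x)) return(NA_real_)
  suppressWarnings(as.numeric(x))
}

read_tsv_meta <- function(path) {
  if (!file.exists(path)) abort_validation(paste0("file not found: ", path))
  lines <- readLines(path, n = 200L)
  hdr <- lines[startsWith(lines, "#")]
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#", "", h)
    k <- sub(":.*$", "", kv)
    meta[[k]] <- strsplit(sub("^[^:]*:[ ]?", "", kv), "\t", fixed = TRUE)[[1]]
  }
  df <- as.data.frame(data.table::fread(path, sep = "\t", skip = length(hdr),
                                        header = TRUE))
  list(data = df, meta = meta)
}

#' Read a genotype matrix from disk
#'
#' Tab-delimited dialect: one row per sample with columns `sample_id`,
#' `population`, then one integer dosage column per SNP (header = SNP ids).
#' SNP metadata (id, chrom, pos, ref, alt, info, maf) comes from the sidecar
#' file written by [write_genotypes()], or defaults when absent.
#'
#' VCF dialect: dosage is the alternate-allele count of the GT field;
#' multi-allelic records are skipped with a warning, missing genotypes
#' become `NA` and are counted in a message.
#'
#' @param path Path to the genotype file.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @param meta_path Path of the SNP metadata sidecar (tsv only); default
#'   `<path>.snps`.
#' @return A `genotype_dataset`.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"),
                           meta_path = paste0(path, ".snps")) {
  format <- match.arg(format)
  if (format == "vcf") return(read_genotypes_vcf(path))
  got <- read_tsv_meta(path)
  df <- got$data
  if (!all(c("sample_id", "population") %in% names(df)))
    abort_data("genotype file must start with columns sample_id, population")
  snp_ids <- setdiff(names(df), c("sample_id", "population"))
  if (!length(snp_ids)) abort_data("genotype file contains no SNP columns")
  g <- as.matrix(df[, snp_ids, drop = FALSE])
  if (!all(g[!is.na(g)] %in% c(0L, 1L, 2L)))
    abort_data("dosages must be 0, 1, 2 or missing")
  storage.mode(g) <- "integer"
  dimnames(g) <- list(df$sample_id, snp_ids)
  if (file.exists(meta_path)) {
    snp_meta <- read_tsv_meta(meta_path)$data
    need <- c("id", "chrom", "pos", "ref", "alt", "info", "maf")
    missing_cols <- setdiff(need, names(snp_meta))
    if (length(missing_cols))
      abort_data(paste0("SNP metadata missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
    snp_meta <- snp_meta[match(snp_ids, snp_meta$id), , drop = FALSE]
    if (anyNA(snp_meta$id)) abort_data("SNP metadata does not cover all SNP columns")
  } else {
    f <- colMeans(g, na.rm = TRUE) / 2
    snp_meta <- data.frame(id = snp_ids, chrom = NA_integer_, pos = NA_real_,
                           ref = NA_character_, alt = NA_character_,
                           info = 1.0, maf = pmin(f, 1 - f),
                           stringsAsFactors = FALSE)
  }
  rownames(snp_meta) <- NULL
  new_genotype_dataset(g, df$sample_id, df$population, snp_meta)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort_validation("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic VCF record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- gsub("[|/]", "", gt)  # e.g. "01", "11", ".."
  counts <- nchar(gsub("[^1]", "", alleles))
  counts[grepl("\\.", gt) | is.na(gt)] <- NA_integer_
  dos <- t(matrix(as.integer(counts), nrow = nrow(gt)))
  n_missing <- sum(is.na(dos))
  if (n_missing > 0)
    message(n_missing, " missing genotype call(s) set to NA")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  f <- colMeans(dos, na.rm = TRUE) / 2
  snp_meta <- data.frame(id = ids, chrom = fix[, "CHROM"],
                         pos = as.numeric(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         info = 1.0, maf = pmin(f, 1 - f),
                         stringsAsFactors = FALSE)
  dimnames(dos) <- list(colnames(gt), ids)
  new_genotype_dataset(dos, colnames(gt), rep(NA_character_, ncol(gt)), snp_meta)
}

#' Write a genotype dataset to disk
#'
#' Writes the sample-by-SNP dosage matrix (with `sample_id` and
#' `population` leading columns) and the SNP metadata sidecar. The pair
#' round-trips bit-identically through [read_genotypes()].
#'
#' @param geno `genotype_dataset`.
#' @param path Output path for the dosage matrix.
#' @param meta_path Output path for SNP metadata (default `<path>.snps`).
#' @export
write_genotypes <- function(geno, path, meta_path = paste0(path, ".snps")) {
  df <- data.frame(sample_id = geno$sample_ids,
                   population = geno$pop_labels,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(geno$dosages))
  write_tsv_meta(df, path)
  write_tsv_meta(geno$snp_meta, meta_path)
  invisible(path)
}

#' Read / write association summary statistics
#'
#' Tab-delimited with a `#kind` header (`gwas` or `pcas`). GWAS columns:
#' `id`, `chrom`, `pos`, `ref`, `alt`, `beta`, `se`, `pvalue`, `n`; PCAS
#' columns: `id`, `beta`, `se`, `pvalue`, `n`. Floating point is written at
#' full precision.
#'
#' @param stats A `summary_stats` object.
#' @param path File path.
#' @return `read_summary_stats()` returns a `summary_stats`;
#'   `write_summary_stats()` returns `path` invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  write_tsv_meta(as.data.frame(stats), path,
                 meta = list(kind = attr(stats, "kind"),
                             covariates = attr(stats, "covariate_names")))
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  got <- read_tsv_meta(path)
  df <- got$data
  need <- c("id", "beta", "se", "pvalue", "n")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    abort_data(paste0("summary statistics missing required column(s): ",
                      paste(missing_cols, collapse = ", ")))
  if (!"tested" %in% names(df)) df$tested <- !is.na(df$beta)
  if (!"note" %in% names(df)) df$note <- NA_character_
  new_summary_stats(df, kind = got$meta$kind %||% "gwas",
                    covariate_names = got$meta$covariates %||% character())
}

#' Read / write map-PC loadings
#'
#' One row per reference SNP: `id`, `chrom`, `pos`, `ref`, `alt`, `center`,
#' `scale`, `loading_1` ... `loading_p`; header lines carry `n_pcs` and the
#' per-PC explained variance.
#'
#' @param loadings A `map_loadings` object.
#' @param path File path.
#' @param snp_meta Optional SNP metadata to embed coordinates (defaults to
#'   blank coordinates).
#' @return `read_map_loadings()` returns a `map_loadings`.
#' @export
write_map_loadings <- function(loadings, path, snp_meta = NULL) {
  p <- loadings$n_pcs
  lt <- t(loadings$loadings)
  colnames(lt) <- paste0("loading_", seq_len(p))
  ids <- loadings$snp_ids
  if (is.null(snp_meta)) {
    snp_meta <- data.frame(id = ids, chrom = NA_integer_, pos = NA_real_,
                           ref = NA_character_, alt = NA_character_,
                           stringsAsFactors = FALSE)
  }
  mrow <- snp_meta[match(ids, snp_meta$id), c("id", "chrom", "pos", "ref", "alt")]
  df <- cbind(mrow, center = unname(loadings$center),
              scale = unname(loadings$scale), as.data.frame(lt))
  write_tsv_meta(df, path,
                 meta = list(n_pcs = p,
                             explained_variance =
                               format(loadings$explained_variance, digits = 17)))
  invisible(path)
}

#' @rdname write_map_loadings
#' @export
read_map_loadings <- function(path) {
  got <- read_tsv_meta(path)
  df <- got$data
  p <- as.integer(got$meta$n_pcs)
  lcols <- paste0("loading_", seq_len(p))
  missing_cols <- setdiff(c("id", "center", "scale", lcols), names(df))
  if (length(missing_cols))
    abort_data(paste0("loadings file missing column(s): ",
                      paste(missing_cols, collapse = ", ")))
  structure(list(snp_ids = df$id,
                 loadings = t(as.matrix(df[, lcols, drop = FALSE])),
                 center = setNames(df$center, df$id),
                 scale = setNames(df$scale, df$id),
                 n_pcs = p,
                 explained_variance = as.numeric(got$meta$explained_variance)),
            class = "map_loadings")
}

#' Read / write a PGS formula (weight file)
#'
#' Generic PGS weight-file layout: columns `id`, `effect_allele`, `weight`;
#' header lines carry the selected p-value threshold and clumping
#' parameters.
#'
#' @param formula A `pgs_formula`.
#' @param path File path.
#' @export
write_pgs_formula <- function(formula, path) {
  df <- data.frame(id = formula$snp_ids,
                   effect_allele = formula$effect_alleles,
                   weight = unname(formula$weights),
                   stringsAsFactors = FALSE)
  write_tsv_meta(df, path,
                 meta = list(p_threshold = format(formula$p_threshold, digits = 17),
                             clump_window_kb = formula$clump_window_kb,
                             clump_r2 = formula$clump_r2))
  invisible(path)
}

#' @rdname write_pgs_formula
#' @export
read_pgs_formula <- function(path) {
  got <- read_tsv_meta(path)
  df <- got$data
  missing_cols <- setdiff(c("id", "effect_allele", "weight"), names(df))
  if (length(missing_cols))
    abort_data(paste0("PGS formula missing column(s): ",
                      paste(missing_cols, collapse = ", ")))
  structure(list(snp_ids = df$id, effect_alleles = df$effect_allele,
                 weights = setNames(df$weight, df$id),
                 p_threshold = meta_number(got$meta$p_threshold),
                 clump_window_kb = meta_number(got$meta$clump_window_kb),
                 clump_r2 = meta_number(got$meta$clump_r2),
                 calibration_r2_by_threshold = NULL),
            class = "pgs_formula")
}

#' Read / write score vectors and phenotype tables
#'
#' Scores: columns `sample_id`, `value` with a `#kind` header (`pgs` or
#' `as`). Phenotypes: columns `sample_id`, `y`, `y_genetic`, `y_env`,
#' `population`.
#'
#' @param scores A `score_vector`.
#' @param path File path.
#' @export
write_scores <- function(scores, path) {
  write_tsv_meta(as.data.frame(scores), path,
                 meta = list(kind = attr(scores, "kind")))
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  got <- read_tsv_meta(path)
  missing_cols <- setdiff(c("sample_id", "value"), names(got$data))
  if (length(missing_cols))
    abort_data(paste0("score file missing column(s): ",
                      paste(missing_cols, collapse = ", ")))
  new_score_vector(got$data$sample_id, got$data$value,
                   kind = got$meta$kind %||% "pgs")
}

#' @rdname write_scores
#' @param pheno A `sim_phenotype`.
#' @param pop_labels Per-sample population labels to embed.
#' @export
write_phenotypes <- function(pheno, path, pop_labels = NULL) {
  df <- data.frame(sample_id = names(pheno$y), y = unname(pheno$y),
                   y_genetic = unname(pheno$y_genetic),
                   y_env = unname(pheno$y_env),
                   population = pop_labels %||% NA_character_,
                   stringsAsFactors = FALSE)
  write_tsv_meta(df, path, meta = list(h2 = pheno$h2))
  invisible(path)
}

#' Write an allele-frequency table / causal-effect truth table
#'
#' @param af_table An `af_table`.
#' @param path File path.
#' @export
write_af_table <- function(af_table, path) {
  write_tsv_meta(as.data.frame(af_table), path)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON snapshot of the configuration, master seed, package version,
#' timestamps and md5 digests of the files produced - enough to verify a
#' byte-identical rerun.
#'
#' @param dir Output directory (one manifest per pipeline output directory).
#' @param config The `scenario_config` (or any serializable config list).
#' @param seed Master seed used.
#' @param files Character vector of produced files to digest.
#' @export
write_run_manifest <- function(dir, config, seed, files = character()) {
  manifest <- list(
    package = "ancestryscore",
    version = as.character(utils::packageVersion("ancestryscore")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(config),
    files = if (length(files))
      lapply(setNames(as.list(files), basename(files)),
             function(f) list(md5 = unname(tools::md5sum(f)))) else list()
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
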