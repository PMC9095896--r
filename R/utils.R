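# Internal helpers shared across modules.

# Error conditions: "validation" for malformed arguments/config, "data" for
# well-formed inputs whose content is unusable. The CLI maps these to exit
# codes 2 and 3.
abort_validation <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("ancestryscore_validation_error", "error"),
                      call = call))
}

abort_data <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("ancestryscore_data_error", "error"),
                      call = call))
}

# Column means/sds of a numeric matrix without materializing scale() copies.
col_means <- function(x) colMeans(x)

col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) abort_validation("need at least 2 rows to compute column SDs")
  m <- colMeans(x)
  v <- (colSums(x * x) - n * m * m) / (n - 1)
  sqrt(pmax(v, 0))
}

# Standardize columns of g with given center/scale, as a dense double matrix.
standardize_dosages <- function(g, center, scale) {
  x <- sweep(g, 2L, center, "-")
  sweep(x, 2L, scale, "/")
}

# Deterministic integer allocation of n samples to named proportions:
# floor + largest-remainder, ties broken by element order.
allocate_counts <- function(n, prop) {
  raw <- n * prop / sum(prop)
  cnt <- floor(raw)
  left <- n - sum(cnt)
  if (left > 0) {
    ord <- order(-(raw - cnt), seq_along(raw))
    cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1L
  }
  as.integer(cnt)
}

# Replicate seeds derived deterministically from a master seed; kept within
# 32-bit integer range.
derive_seeds <- function(master_seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  seeds
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
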