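# Internal helpers: classed conditions, validation, and the vectorized
# least-squares screen shared by the expression and region-methylation scans.

.datatable.aware <- TRUE

hma_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hmakit_error", "error", "condition")))
}

input_error  <- function(msg) hma_error(msg, "hmakit_input_error")
config_error <- function(msg) hma_error(msg, "hmakit_config_error")
fit_error    <- function(msg) hma_error(msg, "hmakit_fit_error")
format_error <- function(msg) hma_error(msg, "hmakit_format_error")
design_error <- function(msg) hma_error(msg, "hmakit_design_error")

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) input_error(sprintf("non-finite values in %s", what))
  invisible(x)
}

#' @importFrom stats pt p.adjust
NULL

# Per-feature ordinary least squares of a feature matrix (features x samples)
# on an arbitrary design matrix, returning the coefficient, standard error,
# two-sided t-test p-value for one column of interest, all computed through a
# single QR decomposition. Constant (zero-residual-variance) features get
# se = 0 and p = 1 with a flag, matching the screen contract.
ols_screen <- function(Y, X, coef_name) {
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  n <- ncol(Y)
  if (nrow(X) != n) input_error("design matrix rows must match sample count")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) input_error("design matrix is rank deficient (confounded covariates)")
  coefs <- t(qr.coef(qrX, t(Y)))              # features x p
  fitted <- coefs %*% t(X)
  res <- Y - fitted
  df <- n - ncol(X)
  if (df < 1) input_error("no residual degrees of freedom")
  s2 <- rowSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  j <- match(coef_name, colnames(X))
  if (is.na(j)) input_error(sprintf("coefficient '%s' not in design", coef_name))
  se <- sqrt(s2 * xtx_inv[j, j])
  beta <- coefs[, j]
  tstat <- ifelse(se > 0, beta / se, 0)
  p <- ifelse(se > 0, 2 * pt(abs(tstat), df, lower.tail = FALSE), 1)
  constant <- s2 <= .Machine$double.eps * 100
  # exact-fit features (zero residual but nonzero effect) keep p ~ 0
  exact <- constant & abs(beta) > 1e-12
  p[constant & !exact] <- 1
  p[exact] <- 0
  data.frame(
    feature_id = rownames(Y) %||% as.character(seq_len(nrow(Y))),
    coefficient = beta,
    se = se,
    t = tstat,
    p_value = p,
    constant_flag = constant & !exact,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seed derivation: keep derived seeds valid 32-bit integers.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587L + 1)
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  data.table::fread(path, sep = "\t", data.table = FALSE, ...)
}
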