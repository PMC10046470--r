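#' Normalized area under a dose-response curve
#'
#' Integrates mean viability over log10(dose) with the trapezoidal rule and
#' divides by the log-dose range, so a fully viable line scores 1 and a line
#' killed at every dose scores 0. Lower AUC therefore means higher
#' sensitivity, the orientation used throughout the package.
#'
#' @param doses strictly increasing positive concentrations (nM); at least 4
#'   distinct values.
#' @param viabilities numeric vector (one value per dose) or matrix with one
#'   row per dose and one column per replicate; replicate values are averaged
#'   per dose before integration. Values are fractions relative to vehicle and
#'   must be >= 0.
#' @return normalized AUC in `[0, 1]`.
#' @examples
#' compute_auc(c(1, 10, 100, 1000), rep(1, 4))   # 1
#' compute_auc(c(1, 10, 100, 1000), rep(0, 4))   # 0
#' @export
compute_auc <- function(doses, viabilities) {
  doses <- as.numeric(doses)
  if (length(unique(doses)) < 4) input_error("at least 4 distinct doses required")
  if (any(!is.finite(doses)) || any(doses <= 0)) input_error("doses must be positive and finite")
  if (is.unsorted(doses, strictly = TRUE)) input_error("doses must be strictly increasing")
  v <- if (is.matrix(viabilities)) rowMeans(viabilities) else as.numeric(viabilities)
  if (length(v) != length(doses)) input_error("viabilities must align with doses")
  if (any(!is.finite(v)) || any(v < 0)) input_error("viabilities must be finite and >= 0")
  x <- log10(doses)
  auc <- sum(diff(x) * (head(v, -1) + tail(v, -1)) / 2) / (max(x) - min(x))
  min(max(auc, 0), 1)
}

#' Four-parameter logistic IC50 fit
#'
#' Fits viability = bottom + (top - bottom) / (1 + (dose / ec50)^slope) on
#' log10(dose) by least squares (bottom bounded at 0, top free) and reports
#' the concentration at which fitted viability reaches 50% of the fitted top.
#' When the fitted curve never crosses that level within the assayed range the
#' IC50 is right-censored at the maximum dose.
#'
#' A coarse grid search over (ec50, slope) seeds the nonlinear fit and serves
#' as fallback when `nls` does not converge.
#'
#' @inheritParams compute_auc
#' @return list with `ic50` (nM), `censored` (logical), and the fitted
#'   parameters `top`, `bottom`, `ec50`, `slope`, plus `rss`.
#' @export
fit_ic50 <- function(doses, viabilities) {
  doses <- as.numeric(doses)
  if (length(unique(doses)) < 4) input_error("at least 4 distinct doses required")
  if (any(doses <= 0)) input_error("doses must be positive")
  v <- if (is.matrix(viabilities)) rowMeans(viabilities) else as.numeric(viabilities)
  if (any(!is.finite(v)) || any(v < 0)) input_error("viabilities must be finite and >= 0")
  ld <- log10(doses)

  pred <- function(p, x) p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
    (1 + 10^((x - p[["lec50"]]) * p[["slope"]]))
  sse <- function(p) sum((v - pred(p, ld))^2)

  # grid seed: log-ec50 across (and one decade beyond) the dose range
  grid <- expand.grid(
    lec50 = seq(min(ld) - 1, max(ld) + 1, length.out = 25),
    slope = c(0.5, 1, 1.5, 2, 3, 4)
  )
  grid_sse <- vapply(seq_len(nrow(grid)), function(i) {
    sse(c(top = max(v), bottom = max(0, min(v)),
          lec50 = grid$lec50[i], slope = grid$slope[i]))
  }, numeric(1))
  g <- grid[which.min(grid_sse), ]
  start <- c(top = max(v), bottom = max(0, min(v)), lec50 = g$lec50, slope = g$slope)

  opt <- tryCatch(
    optim(start, sse, method = "L-BFGS-B",
          lower = c(top = 0.05, bottom = 0, lec50 = min(ld) - 3, slope = 0.05),
          upper = c(top = max(v) * 1.5 + 0.1, bottom = max(v), lec50 = max(ld) + 4, slope = 10)),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    fit_error("IC50 fit failed to converge (grid + L-BFGS-B); inspect the curve")
  }
  p <- opt$par
  if (p[["bottom"]] > p[["top"]]) { tmp <- p[["bottom"]]; p[["bottom"]] <- p[["top"]]; p[["top"]] <- tmp }
  half <- p[["top"]] / 2
  out <- list(top = unname(p[["top"]]), bottom = unname(p[["bottom"]]),
              ec50 = unname(10^p[["lec50"]]), slope = unname(p[["slope"]]),
              rss = opt$value)
  if (p[["bottom"]] >= half) {
    out$ic50 <- max(doses); out$censored <- TRUE
    return(out)
  }
  # viability(x) = half  =>  (d/ec50)^slope = (top - half)/(half - bottom)
  ratio <- (p[["top"]] - half) / (half - p[["bottom"]])
  ic50 <- 10^(p[["lec50"]] + log10(ratio) / p[["slope"]])
  if (ic50 > max(doses)) {
    out$ic50 <- max(doses); out$censored <- TRUE
  } else {
    out$ic50 <- ic50; out$censored <- FALSE
  }
  out
}

#' Flag sensitive cell lines (lowest 50% AUC)
#'
#' A line is sensitive when its AUC is at or below the panel median; ties at
#' the median count as sensitive.
#'
#' @param records data.frame with columns `cell_line` and `auc`.
#' @return `records` with a logical `sensitive` column added.
#' @export
flag_sensitive <- function(records) {
  auc <- records$auc
  ok <- is.finite(auc)
  if (sum(ok) < 2) input_error("need at least 2 finite AUC values")
  med <- median(auc[ok])
  records$sensitive <- ifelse(ok, auc <= med, NA)
  records
}

#' Tissue enrichment odds ratio for sensitivity
#'
#' Builds the 2x2 table (sensitive/insensitive x in-tissue/out-of-tissue) and
#' reports the odds ratio with a Haldane-Anscombe +0.5 correction when any
#' cell is zero, a Wald 95% CI on the log odds ratio, a two-sided Fisher exact
#' p-value, and (because the convention differs between forest-plot tools) a
#' chi-square p-value as well.
#'
#' @param records data.frame with `tissue` and logical `sensitive` columns.
#' @param tissue tissue name to test.
#' @return one-row data.frame with `tissue`, `odds_ratio`, `ci95_low`,
#'   `ci95_high`, `p_value` (Fisher), `p_chisq`, and counts `a`, `b`, `c`,
#'   `d`.
#' @export
tissue_odds_ratio <- function(records, tissue) {
  if (is.null(records$sensitive)) input_error("run flag_sensitive() first")
  if (!tissue %in% records$tissue) input_error(sprintf("tissue '%s' absent from table", tissue))
  keep <- !is.na(records$sensitive)
  s <- records$sensitive[keep]
  tin <- records$tissue[keep] == tissue
  a <- sum(s & tin); b <- sum(!s & tin); c <- sum(s & !tin); d <- sum(!s & !tin)
  odds_ratio_2x2(a, b, c, d, tissue = tissue)
}

# Shared 2x2 machinery (also used by the mutation-screen fallback).
odds_ratio_2x2 <- function(a, b, c, d, tissue = NA_character_) {
  corr <- if (any(c(a, b, c, d) == 0)) 0.5 else 0
  aa <- a + corr; bb <- b + corr; cc <- c + corr; dd <- d + corr
  or <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  ci <- exp(log(or) + c(-1, 1) * qnorm(0.975) * se)
  tab <- matrix(c(a, b, c, d), nrow = 2)
  p_fisher <- fisher.test(tab)$p.value
  p_chisq <- tryCatch(suppressWarnings(chisq.test(tab, correct = FALSE)$p.value),
                      error = function(e) NA_real_)
  data.frame(tissue = tissue, odds_ratio = or, ci95_low = ci[1], ci95_high = ci[2],
             p_value = p_fisher, p_chisq = p_chisq,
             a = a, b = b, c = c, d = d, stringsAsFactors = FALSE)
}

#' Classify responders and nonresponders by AUC tertile
#'
#' Sorts lines by AUC (ties broken by cell-line identifier, so the
#' classification is stable and reproducible); the lowest `floor(n/3)` become
#' responders, the highest `floor(n/3)` nonresponders, and everything in
#' between is labelled intermediate and excluded from downstream screens.
#' Lines with missing AUC are `unclassified`.
#'
#' @param records data.frame with `cell_line` and `auc`.
#' @return `records` with a `response_class` factor column
#'   (responder/intermediate/nonresponder/unclassified).
#' @export
classify_responders <- function(records) {
  auc <- records$auc
  ok <- which(is.finite(auc))
  n <- length(ok)
  if (n < 3) input_error("need at least 3 finite AUC values for a tertile split")
  if (length(unique(auc[ok])) == 1) {
    warning("all AUC values identical; tertile classes determined by identifier order")
  }
  k <- floor(n / 3)
  ord <- ok[order(auc[ok], records$cell_line[ok])]
  cls <- rep("unclassified", nrow(records))
  cls[ord] <- "intermediate"
  cls[ord[seq_len(k)]] <- "responder"
  cls[ord[seq.int(n - k + 1, n)]] <- "nonresponder"
  records$response_class <- factor(cls, levels = c("responder", "intermediate",
                                                   "nonresponder", "unclassified"))
  records
}

#' Correlate a per-cell-line feature with a sensitivity metric
#'
#' Pearson correlation on complete pairs, with an optional log2 transform of
#' the feature (used e.g. for mutation burden), and a two-sided p-value from
#' the t distribution.
#'
#' @param metric numeric sensitivity metric per line (AUC or log2 IC50).
#' @param feature numeric feature per line, aligned with `metric`.
#' @param transform `"identity"` or `"log2"` (applied to the feature as
#'   `log2(x + 1)` so zero counts are representable).
#' @return list with `r`, `p_value`, `n`.
#' @export
correlate_feature <- function(metric, feature, transform = c("identity", "log2")) {
  transform <- match.arg(transform)
  if (transform == "log2") feature <- log2(feature + 1)
  ok <- is.finite(metric) & is.finite(feature)
  if (sum(ok) < 3) input_error("need at least 3 complete pairs")
  x <- metric[ok]; y <- feature[ok]
  if (sd(x) == 0 || sd(y) == 0) input_error("undefined correlation: zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' @importFrom stats median qnorm fisher.test chisq.test cor.test sd optim
#' @importFrom utils head tail
NULL
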