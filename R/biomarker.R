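# Responder/nonresponder association screens with a hematopoietic-lineage
# covariate, plus the permutation-validated region-set score.

# Build the (intercept, group, lineage) design shared by the screens.
screen_design <- function(classes, lineage) {
  classes <- as.character(classes)
  use <- classes %in% c("responder", "nonresponder")
  if (sum(classes[use] == "responder") < 3 || sum(classes[use] == "nonresponder") < 3) {
    input_error("need >= 3 cell lines per response class")
  }
  X <- cbind(intercept = 1,
             group = as.numeric(classes[use] == "nonresponder"),
             lineage = as.numeric(lineage[use]))
  list(X = X, use = use)
}

finish_screen <- function(res) {
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res$direction <- ifelse(res$coefficient < 0, "sensitivity_associated",
                          "resistance_associated")
  res[order(res$p_value), ]
}

#' Differential expression between responders and nonresponders
#'
#' Per gene, least-squares fit of (log2) expression on the nonresponder
#' indicator plus a binary hematopoietic-lineage covariate; the reported
#' coefficient is the covariate-adjusted NR - R difference (so negative
#' coefficients are sensitivity-associated). Two-sided t-test on the group
#' coefficient, Benjamini-Hochberg adjustment across genes. Intermediate and
#' unclassified lines are excluded.
#'
#' @param expr gene x cell-line matrix (log2 scale), colnames = cell lines.
#' @param classes response classes aligned with `colnames(expr)` (from
#'   [classify_responders()]).
#' @param lineage logical/0-1 hematopoietic flag aligned with columns.
#' @return data.frame of per-gene results: `feature_id`, `coefficient`, `se`,
#'   `p_value`, `p_adjusted`, `direction`, `constant_flag`, sorted by p.
#' @export
differential_expression <- function(expr, classes, lineage) {
  d <- screen_design(classes, lineage)
  res <- ols_screen(expr[, d$use, drop = FALSE], d$X, "group")
  finish_screen(res)
}

#' Filter a mutation matrix to a driver-gene whitelist
#'
#' With `whitelist = NULL` the matrix is returned unchanged with a warning
#' (no passenger filtering applied).
#'
#' @param mutations binary gene x cell-line matrix.
#' @param whitelist character vector of gene names, or NULL.
#' @return the filtered matrix.
#' @export
filter_mutations <- function(mutations, whitelist = NULL) {
  if (is.null(whitelist)) {
    warning("no whitelist supplied; passenger mutations not filtered")
    return(mutations)
  }
  keep <- rownames(mutations) %in% whitelist
  if (!any(keep)) input_error("whitelist removes every gene from the mutation matrix")
  mutations[keep, , drop = FALSE]
}

#' Mutation association with response class
#'
#' Per gene, a logistic regression of mutation status on the nonresponder
#' indicator plus the lineage covariate. Negative coefficients mean the
#' mutation skews toward responders; `odds_ratio = exp(coefficient)`. On
#' (quasi-)separation the model falls back to a Haldane-corrected 2x2 odds
#' ratio stratified by lineage (inverse-variance combined on the log scale)
#' with a Fisher exact p from the pooled table, and flags the fallback.
#' Genes mutated in fewer than 2 lines are skipped.
#'
#' @inheritParams differential_expression
#' @param mutations binary gene x cell-line matrix.
#' @return data.frame with `feature_id`, `coefficient` (log-OR), `odds_ratio`,
#'   `p_value`, `p_adjusted`, `direction`, `fallback_flag`.
#' @export
mutation_association <- function(mutations, classes, lineage) {
  classes <- as.character(classes)
  use <- classes %in% c("responder", "nonresponder")
  grp <- as.numeric(classes[use] == "nonresponder")
  lin <- as.numeric(lineage[use])
  M <- mutations[, use, drop = FALSE]
  rows <- lapply(rownames(M), function(g) {
    y <- as.numeric(M[g, ])
    if (sum(y) < 2) return(NULL)   # skipped with flag (absent from output)
    fit <- suppressWarnings(glm(y ~ grp + lin, family = binomial()))
    coef_g <- coef(fit)[["grp"]]
    se_g <- suppressWarnings(sqrt(diag(vcov(fit)))[["grp"]])
    separated <- !fit$converged || !is.finite(se_g) || se_g > 10 || abs(coef_g) > 10
    if (!separated) {
      p <- 2 * pnorm(abs(coef_g / se_g), lower.tail = FALSE)
      data.frame(feature_id = g, coefficient = coef_g, odds_ratio = exp(coef_g),
                 p_value = p, fallback_flag = FALSE, stringsAsFactors = FALSE)
    } else {
      st <- stratified_or(y, grp, lin)
      data.frame(feature_id = g, coefficient = log(st$or), odds_ratio = st$or,
                 p_value = st$p, fallback_flag = TRUE, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) input_error("no gene mutated in >= 2 cell lines")
  finish_screen(res)
}

# Haldane-corrected per-stratum ORs combined by inverse-variance weighting;
# Fisher p from the pooled (collapsed) table. OR orientation: odds of
# mutation in nonresponders over responders, matching the logistic coding.
stratified_or <- function(y, grp, lin) {
  logors <- c(); ws <- c()
  for (s in unique(lin)) {
    i <- lin == s
    a <- sum(y[i] == 1 & grp[i] == 1); b <- sum(y[i] == 0 & grp[i] == 1)
    c_ <- sum(y[i] == 1 & grp[i] == 0); d <- sum(y[i] == 0 & grp[i] == 0)
    if ((a + b) == 0 || (c_ + d) == 0) next  # stratum lacks one group
    aa <- a + 0.5; bb <- b + 0.5; cc <- c_ + 0.5; dd <- d + 0.5
    v <- 1 / aa + 1 / bb + 1 / cc + 1 / dd
    logors <- c(logors, log((aa * dd) / (bb * cc)))
    ws <- c(ws, 1 / v)
  }
  or <- exp(sum(logors * ws) / sum(ws))
  a <- sum(y == 1 & grp == 1); b <- sum(y == 0 & grp == 1)
  c_ <- sum(y == 1 & grp == 0); d <- sum(y == 0 & grp == 0)
  p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2))$p.value
  list(or = or, p = p)
}

#' Per-cell-line mutation burden
#'
#' @param mutations binary gene x cell-line matrix.
#' @param transform `"identity"` or `"log2"` for `log2(count + 1)`.
#' @return named numeric vector of counts (or transformed counts).
#' @export
mutation_burden <- function(mutations, transform = c("identity", "log2")) {
  transform <- match.arg(transform)
  if (!all(mutations %in% c(0, 1))) input_error("mutation matrix must be binary")
  counts <- colSums(mutations)
  if (transform == "log2") log2(counts + 1) else counts
}

#' Differential promoter methylation between responders and nonresponders
#'
#' The same covariate-adjusted least-squares screen as
#' [differential_expression()], applied to region-level mean beta-values
#' (mean beta of member probes, precomputed). Regions hypermethylated in
#' responders have negative NR - R coefficients and are the
#' sensitivity-associated candidates.
#'
#' @param region_meth region x cell-line matrix of mean beta-values.
#' @inheritParams differential_expression
#' @return as [differential_expression()].
#' @export
differential_methylation_regions <- function(region_meth, classes, lineage) {
  differential_expression(region_meth, classes, lineage)
}

#' Aggregate probe beta-values to region means
#'
#' @param beta probe x sample matrix.
#' @param region_map data.frame with `probe_id`, `region_id`.
#' @return region x sample matrix of mean beta per region.
#' @export
region_means <- function(beta, region_map) {
  idx <- match(region_map$probe_id, rownames(beta))
  if (any(is.na(idx))) input_error("region map references probes absent from beta matrix")
  dt <- data.table::data.table(region = region_map$region_id, beta[idx, , drop = FALSE])
  agg <- dt[, lapply(.SD, mean), by = region]
  m <- as.matrix(agg[, -1])
  rownames(m) <- agg$region
  m
}

#' Score a region set against IC50
#'
#' Per cell line, the mean beta across the set's regions is correlated
#' (Pearson) with log2(IC50). Lines with censored or missing IC50 are
#' excluded (count reported). The expected sign for a hypermethylation
#' sensitivity marker is negative: higher methylation, lower IC50.
#'
#' @param region_set character vector of region ids.
#' @param region_meth region x cell-line mean-beta matrix.
#' @param ic50 per-line IC50 (nM), aligned with columns; NA = censored.
#' @return list with `region_ids`, `mean_methylation` (per line),
#'   `r_observed`, `p_value`, `n_lines`, `n_excluded`.
#' @export
region_set_score <- function(region_set, region_meth, ic50) {
  if (!length(region_set)) input_error("empty region set")
  missing_regions <- setdiff(region_set, rownames(region_meth))
  if (length(missing_regions)) input_error("region set not contained in matrix")
  mm <- colMeans(region_meth[region_set, , drop = FALSE])
  ok <- is.finite(ic50) & ic50 > 0
  if (sum(ok) < 3) input_error("need >= 3 lines with finite IC50")
  if (sd(mm[ok]) == 0) input_error("undefined correlation: constant mean methylation")
  ct <- cor.test(mm[ok], log2(ic50[ok]), method = "pearson")
  list(region_ids = region_set, mean_methylation = mm,
       r_observed = unname(ct$estimate), p_value = ct$p.value,
       n_lines = sum(ok), n_excluded = sum(!ok))
}

#' Permutation null for the region-set score
#'
#' Draws `n_iterations` random region sets of the observed size (uniformly,
#' without replacement within a draw) from the candidate universe, computes
#' the mean-methylation/log2(IC50) correlation for each, and reports the
#' add-one empirical p-value
#' `(1 + #\{|r_null| >= |r_observed|\}) / (1 + n_iterations)`, which can never
#' be exactly zero. Two-sided on |r|.
#'
#' @param region_set_size size of each random set.
#' @param universe candidate region ids (rows of `region_meth`).
#' @param region_meth region x cell-line mean-beta matrix.
#' @param ic50 per-line IC50 (NA = censored, excluded).
#' @param r_observed observed correlation to test.
#' @param n_iterations number of random draws (paper-scale 1e5; tests use
#'   1e3-1e4).
#' @param seed integer seed; the draw sequence is fully reproducible.
#' @return list with `empirical_p`, `n_iterations`, `universe_size`,
#'   `null_summary` (quantiles of the null |r|), `r_null` (the draws).
#' @export
permutation_null <- function(region_set_size, universe, region_meth, ic50,
                             r_observed, n_iterations = 1000, seed = 1) {
  if (region_set_size > length(universe)) input_error("set size exceeds universe")
  if (n_iterations < 1) input_error("n_iterations must be >= 1")
  ok <- is.finite(ic50) & ic50 > 0
  y <- log2(ic50[ok])
  B <- region_meth[universe, ok, drop = FALSE]
  set.seed(seed)
  r_null <- numeric(n_iterations)
  chunk <- 2000L
  done <- 0L
  while (done < n_iterations) {
    k <- min(chunk, n_iterations - done)
    # lines x k matrix of random-set mean methylation
    mm <- vapply(seq_len(k), function(i) {
      colMeans(B[sample.int(nrow(B), region_set_size), , drop = FALSE])
    }, numeric(length(y)))
    r_null[done + seq_len(k)] <- suppressWarnings(as.numeric(cor(y, mm)))
    done <- done + k
  }
  r_null[is.na(r_null)] <- 0
  exceed <- sum(abs(r_null) >= abs(r_observed))
  list(empirical_p = (1 + exceed) / (1 + n_iterations),
       n_iterations = n_iterations,
       universe_size = length(universe),
       null_summary = quantile(abs(r_null), c(0.5, 0.9, 0.95, 0.99, 1)),
       r_null = r_null)
}

#' @importFrom stats glm binomial coef vcov pnorm quantile cor
NULL
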