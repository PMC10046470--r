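#' Beta-value from background-subtracted array intensities
#'
#' beta = max(M, 0) / (|U| + |M| + 100). Background subtraction can leave
#' negative signals, hence the max() in the numerator and the absolute values
#' in the denominator; the +100 offset (same arbitrary fluorescence units as M
#' and U) regularizes low-intensity probes and guarantees beta < 1.
#'
#' @param M methylated-allele signal (vectorized).
#' @param U unmethylated-allele signal (vectorized, recycled against `M`).
#' @return beta values in `[0, 1)`.
#' @examples
#' compute_beta(900, 100)  # 900/1100
#' compute_beta(-50, 200)  # 0
#' @export
compute_beta <- function(M, U) {
  if (any(!is.finite(M)) || any(!is.finite(U))) input_error("non-finite intensities")
  pmax(M, 0) / (abs(U) + abs(M) + 100)
}

# The nested delta-beta cutoffs used for DMC calling throughout.
DMC_CUTOFFS <- c(0, -0.05, -0.1, -0.2)

#' Call differentially methylated CpGs against the DMSO control
#'
#' Per probe: delta-beta = mean(treated) - mean(control) and a two-tailed
#' unpaired t-test between the treated and DMSO replicate groups. A probe is
#' flagged demethylated at a cutoff when p < 0.05 and delta-beta is below the
#' cutoff; the four cutoffs (0, -0.05, -0.1, -0.2) give nested flag sets by
#' construction.
#'
#' The default test pools variances (Student); Welch is available via
#' `var_equal = FALSE` since triplicate designs give unstable per-group
#' variance estimates either way.
#'
#' @param beta probe x sample matrix of beta-values with rownames = probe ids.
#' @param design data.frame with columns `sample` (matching `colnames(beta)`),
#'   `condition` (`"DMSO"` or a drug name) and `replicate`.
#' @param drug condition name to test against DMSO.
#' @param var_equal pool variances (default TRUE).
#' @return data.frame with `probe_id`, `delta_beta`, `p_value` and logical
#'   columns `dmc_0`, `dmc_0.05`, `dmc_0.1`, `dmc_0.2`. Probes with any
#'   missing replicate are dropped and counted in the `"n_dropped"` attribute.
#' @export
call_dmcs <- function(beta, design, drug, var_equal = TRUE) {
  if (!"DMSO" %in% design$condition) design_error("design has no DMSO control condition")
  if (!drug %in% design$condition) design_error(sprintf("condition '%s' not in design", drug))
  trt <- design$sample[design$condition == drug]
  ctl <- design$sample[design$condition == "DMSO"]
  if (length(trt) < 2 || length(ctl) < 2) design_error("need >= 2 replicates per condition")
  X <- beta[, trt, drop = FALSE]
  Y <- beta[, ctl, drop = FALSE]
  complete <- rowSums(is.na(X)) == 0 & rowSums(is.na(Y)) == 0
  n_dropped <- sum(!complete)
  X <- X[complete, , drop = FALSE]; Y <- Y[complete, , drop = FALSE]
  n1 <- ncol(X); n2 <- ncol(Y)
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  v1 <- rowSums((X - m1)^2) / (n1 - 1)
  v2 <- rowSums((Y - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  delta <- m1 - m2
  tstat <- ifelse(se > 0, delta / se, 0)
  p <- ifelse(se > 0, 2 * pt(abs(tstat), df, lower.tail = FALSE), 1)
  out <- data.frame(probe_id = rownames(beta)[complete], delta_beta = delta,
                    p_value = p, stringsAsFactors = FALSE, row.names = NULL)
  for (cut in DMC_CUTOFFS) {
    out[[dmc_col(cut)]] <- out$p_value < 0.05 & out$delta_beta < cut
  }
  attr(out, "n_dropped") <- n_dropped
  attr(out, "var_equal") <- var_equal
  out
}

dmc_col <- function(cutoff) paste0("dmc_", sub("^-", "", format(cutoff, trim = TRUE)))

check_cutoff <- function(cutoff) {
  if (!cutoff %in% DMC_CUTOFFS) {
    input_error(sprintf("cutoff must be one of {%s}", paste(DMC_CUTOFFS, collapse = ", ")))
  }
  cutoff
}

#' Shared and drug-specific DMCs at a delta-beta cutoff
#'
#' @param dmcs_a,dmcs_b DMC tables from [call_dmcs()] over the same probe
#'   universe.
#' @param cutoff one of 0, -0.05, -0.1, -0.2.
#' @return list with counts `a_only`, `b_only`, `shared`.
#' @export
shared_dmcs <- function(dmcs_a, dmcs_b, cutoff = 0) {
  check_cutoff(cutoff)
  if (!setequal(dmcs_a$probe_id, dmcs_b$probe_id)) {
    input_error("DMC tables cover different probe universes")
  }
  col <- dmc_col(cutoff)
  sa <- dmcs_a$probe_id[dmcs_a[[col]]]
  sb <- dmcs_b$probe_id[dmcs_b[[col]]]
  list(a_only = length(setdiff(sa, sb)),
       b_only = length(setdiff(sb, sa)),
       shared = length(intersect(sa, sb)))
}

#' Normalized demethylation activity ratio per genomic feature
#'
#' For each feature class: (number of CpGs in the feature demethylated by
#' drug A) / (number demethylated by drug B). Probes without a feature
#' assignment fall into `"unannotated"`. A zero denominator yields NA with a
#' warning rather than infinity.
#'
#' @inheritParams shared_dmcs
#' @param feature_assignment named character vector or data.frame
#'   (`probe_id`, `feature`) mapping probes to feature classes.
#' @return data.frame with `feature`, `n_a`, `n_b`, `ratio`.
#' @export
normalized_demethylation_ratio <- function(dmcs_a, dmcs_b, feature_assignment,
                                           cutoff = 0) {
  check_cutoff(cutoff)
  if (is.data.frame(feature_assignment)) {
    fa <- setNames(as.character(feature_assignment$feature),
                   feature_assignment$probe_id)
  } else {
    fa <- feature_assignment
  }
  col <- dmc_col(cutoff)
  feat_of <- function(ids) {
    f <- fa[ids]
    f[is.na(f)] <- "unannotated"
    f
  }
  universe_features <- sort(unique(feat_of(union(dmcs_a$probe_id, dmcs_b$probe_id))))
  na_ <- table(factor(feat_of(dmcs_a$probe_id[dmcs_a[[col]]]), levels = universe_features))
  nb_ <- table(factor(feat_of(dmcs_b$probe_id[dmcs_b[[col]]]), levels = universe_features))
  ratio <- ifelse(nb_ == 0, NA_real_, as.numeric(na_) / as.numeric(nb_))
  if (any(nb_ == 0 & na_ > 0)) {
    warning("denominator drug has zero DMCs in some feature(s); ratio reported as NA")
  }
  data.frame(feature = universe_features, n_a = as.integer(na_),
             n_b = as.integer(nb_), ratio = ratio,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @importFrom stats setNames
NULL
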