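# Chou-Talalay median-effect modelling and combination indices.
#
# The median-effect line is log10(fa/(1-fa)) = m * (log10(D) - log10(Dm)):
# m is the sigmoidicity slope and Dm the dose giving 50% effect. The
# combination index uses the mutually exclusive two-term form
# CI = d_a/Dx_a + d_b/Dx_b, where Dx = Dm * (fa/(1-fa))^(1/m) is the
# single-agent dose producing the combination's observed effect.

#' Fit a median-effect model to single-agent data
#'
#' Least-squares line of log10(fa/(1-fa)) on log10(dose). Only points with
#' fractional effect strictly inside (0,1) carry information and are used.
#'
#' @param doses positive concentrations (nM).
#' @param fa fraction affected per dose (1 - relative viability), in `[0,1]`.
#' @return list with `m`, `Dm` (nM), `r2`, `n_used`.
#' @export
fit_median_effect <- function(doses, fa) {
  if (any(fa < 0 | fa > 1, na.rm = TRUE)) input_error("fa must lie in [0,1]")
  usable <- is.finite(doses) & is.finite(fa) & doses > 0 & fa > 0 & fa < 1
  if (sum(usable) < 2) fit_error("need >= 2 points with fa strictly in (0,1)")
  x <- log10(doses[usable])
  y <- log10(fa[usable] / (1 - fa[usable]))
  if (length(unique(x)) < 2) fit_error("need >= 2 distinct usable doses")
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2])
  if (!is.finite(m) || m <= 0) fit_error("non-positive median-effect slope; data not dose-responsive")
  Dm <- 10^(-unname(coef(fit)[1]) / m)
  # summary.lm warns on zero-residual (noiseless) input; r2 = 1 is still right
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(m = m, Dm = Dm, r2 = r2, n_used = sum(usable))
}

# Single-agent dose producing fractional effect fa under a median-effect fit.
dose_for_effect <- function(fit, fa) {
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Combination index for one dose pair
#'
#' Mutually exclusive two-term Chou-Talalay form. CI < 1 indicates synergy,
#' CI = 1 additivity, CI > 1 antagonism. Cells with fa of exactly 0 or 1 are
#' unscorable and return NA; a zero/zero dose pair returns CI = 0 and is
#' flagged degenerate by the caller.
#'
#' @param fit_a,fit_b median-effect fits from [fit_median_effect()].
#' @param dose_a,dose_b combination doses (nM).
#' @param fa_combo observed fraction affected of the combination.
#' @return CI value (NA when unscorable).
#' @export
combination_index <- function(fit_a, fit_b, dose_a, dose_b, fa_combo) {
  if (!is.finite(fa_combo) || fa_combo <= 0 || fa_combo >= 1) return(NA_real_)
  dose_a / dose_for_effect(fit_a, fa_combo) +
    dose_b / dose_for_effect(fit_b, fa_combo)
}

#' Score a combination dose matrix
#'
#' Applies [combination_index()] to every cell of a dose grid. Cells whose
#' observed fraction affected falls outside (0,1) (e.g. viability >= vehicle)
#' are left unscored (NA in `ci`, TRUE in `unscored`).
#'
#' @param doses_a,doses_b dose grids (nM) for the two agents.
#' @param fa matrix (length(doses_a) x length(doses_b)) of observed fraction
#'   affected.
#' @param fit_a,fit_b single-agent median-effect fits.
#' @return list with matrices `ci` and `unscored`, plus `fraction_synergistic`
#'   (share of scored cells with CI < 1).
#' @export
score_matrix <- function(doses_a, doses_b, fa, fit_a, fit_b) {
  if (length(doses_a) == 0 || length(doses_b) == 0) {
    return(list(ci = matrix(numeric(0), length(doses_a), length(doses_b)),
                unscored = matrix(logical(0), length(doses_a), length(doses_b)),
                fraction_synergistic = NA_real_))
  }
  stopifnot(nrow(fa) == length(doses_a), ncol(fa) == length(doses_b))
  ci <- matrix(NA_real_, nrow(fa), ncol(fa), dimnames = dimnames(fa))
  for (i in seq_along(doses_a)) {
    for (j in seq_along(doses_b)) {
      ci[i, j] <- combination_index(fit_a, fit_b, doses_a[i], doses_b[j], fa[i, j])
    }
  }
  unscored <- is.na(ci)
  scored <- ci[!unscored]
  list(ci = ci, unscored = unscored,
       fraction_synergistic = if (length(scored)) mean(scored < 1) else NA_real_)
}

#' @importFrom stats lm
NULL
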