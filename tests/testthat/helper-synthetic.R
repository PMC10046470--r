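# Shared fixtures, built in code at test time.

small_panel <- function(seed = 1, n = 60, ...) {
  generate_panel(panel_spec(n_cell_lines = n, seed = seed, ...))
}

# Hand-built sensitivity records for unit tests of the split/OR logic.
make_records <- function(auc, tissue = rep("lung", length(auc)),
                         sensitive = NULL,
                         cell_line = sprintf("CL%03d", seq_along(auc))) {
  df <- data.frame(cell_line = cell_line, tissue = tissue,
                   hematopoietic = tissue == "blood", auc = auc,
                   stringsAsFactors = FALSE)
  if (!is.null(sensitive)) df$sensitive <- sensitive
  df
}

# Noiseless 4PL viability curve.
fourpl <- function(doses, ec50, slope = 1, top = 1, bottom = 0) {
  bottom + (top - bottom) / (1 + (doses / ec50)^slope)
}

# Triplicate methylation experiment from explicit per-condition target betas.
make_experiment <- function(betas_by_condition, probe_ids = NULL) {
  conds <- names(betas_by_condition)
  design <- expand.grid(replicate = 1:3, condition = conds,
                        stringsAsFactors = FALSE)[, 2:1]
  design$sample <- paste0(design$condition, "_", design$replicate)
  n_probes <- length(betas_by_condition[[1]][[1]])
  beta <- do.call(cbind, lapply(conds, function(cn) {
    do.call(cbind, betas_by_condition[[cn]])
  }))
  colnames(beta) <- design$sample
  rownames(beta) <- probe_ids %||% sprintf("cg%04d", seq_len(n_probes))
  list(beta = beta, design = design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
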