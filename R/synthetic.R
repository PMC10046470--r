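# Seeded synthetic multi-omic generator. Emulates the statistical structure
# the downstream stages assume: a cell-line panel with lineage-skewed
# sensitivity, a methylome with responder-hypermethylated promoter regions and
# replication-timing-coupled drug demethylation, and expression/mutation/
# protein matrices with planted (and lineage-confounded) markers. All
# randomness flows from explicit seed fields; no global state is assumed.

#' Panel specification
#'
#' @param n_cell_lines number of cell lines (>= 6).
#' @param tissue_proportions named fractions summing to 1.
#' @param hematopoietic_tissues tissue names counted as hematopoietic lineage.
#' @param auc_shift_hematopoietic signed shift of mean AUC for hematopoietic
#'   lines (negative = more sensitive blood cancers).
#' @param noise_sd standard deviation of per-line AUC noise (> 0).
#' @param base_auc mean AUC of non-hematopoietic lines. The AUC distribution
#'   across a panel is a modeling choice (no canonical shape exists); a
#'   Gaussian around 0.65 keeps most of the panel uncensored while leaving
#'   room for the lineage shift.
#' @param seed integer seed.
#' @return a `panel_spec` list.
#' @export
panel_spec <- function(n_cell_lines = 300,
                       tissue_proportions = c(blood = 0.25, lung = 0.15,
                                              breast = 0.10, skin = 0.10,
                                              CNS = 0.10, colon = 0.10,
                                              kidney = 0.08, ovary = 0.07,
                                              pancreas = 0.05),
                       hematopoietic_tissues = "blood",
                       auc_shift_hematopoietic = -0.15,
                       noise_sd = 0.05,
                       base_auc = 0.65,
                       seed = 1) {
  if (abs(sum(tissue_proportions) - 1) > 1e-9) config_error("tissue proportions must sum to 1")
  if (n_cell_lines < 6) config_error("n_cell_lines must be >= 6")
  if (noise_sd <= 0) config_error("noise_sd must be > 0")
  structure(list(n_cell_lines = as.integer(n_cell_lines),
                 tissue_proportions = tissue_proportions,
                 hematopoietic_tissues = hematopoietic_tissues,
                 auc_shift_hematopoietic = auc_shift_hematopoietic,
                 noise_sd = noise_sd, base_auc = base_auc,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

# 10-point half-log dilution series, 1.5 nM .. 10 uM.
default_doses <- function() 10^seq(log10(1.5), log10(1e4), length.out = 10)

# Invert the normalized trapezoid AUC of a unit-logistic curve
# v(x) = 1/(1 + 10^(x - m)) on the dose grid, solving for m.
auc_to_logec50 <- function(target, log_doses) {
  trap <- function(m) {
    v <- 1 / (1 + 10^(log_doses - m))
    sum(diff(log_doses) * (head(v, -1) + tail(v, -1)) / 2) /
      (max(log_doses) - min(log_doses))
  }
  lo <- min(log_doses) - 6; hi <- max(log_doses) + 6
  uniroot(function(m) trap(m) - target, c(lo, hi), tol = 1e-9)$root
}

#' Generate a synthetic cell-line sensitivity panel
#'
#' Assigns tissues by the spec proportions, draws per-line AUC values
#' (Gaussian, shifted for hematopoietic lines), and constructs 10-dose
#' replicate viability curves whose noiseless normalized AUC equals the
#' planted value (unit-slope logistic with the midpoint solved by root
#' finding). The per-line IC50 is the logistic midpoint, right-censored past
#' the top dose. Doubling time is generated shorter for sensitive lines.
#'
#' @param spec a [panel_spec()].
#' @return list with `records` (cell_line, tissue, hematopoietic, auc, ic50,
#'   ic50_censored, doubling_time) and `curves` (long table: cell_line, drug,
#'   dose, replicate, viability).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  n <- spec$n_cell_lines
  tissues <- names(spec$tissue_proportions)
  counts <- floor(spec$tissue_proportions * n)
  short <- n - sum(counts)
  if (short > 0) {
    frac <- spec$tissue_proportions * n - counts
    top_up <- order(frac, decreasing = TRUE)[seq_len(short)]
    counts[top_up] <- counts[top_up] + 1
  }
  tissue <- sample(rep(tissues, counts))
  hema <- tissue %in% spec$hematopoietic_tissues
  auc <- rnorm(n, spec$base_auc + spec$auc_shift_hematopoietic * hema, spec$noise_sd)
  auc <- pmin(pmax(auc, 0.08), 0.97)

  doses <- default_doses()
  ld <- log10(doses)
  lec50 <- vapply(auc, auc_to_logec50, numeric(1), log_doses = ld)
  ic50 <- 10^lec50
  censored <- ic50 > max(doses)

  cl <- sprintf("CL%03d", seq_len(n))
  # sensitive lines double faster (responders trend hyperproliferative)
  doubling <- 20 + 55 * (auc - min(auc)) / max(diff(range(auc)), 1e-9) + rnorm(n, 0, 5)
  records <- data.frame(cell_line = cl, tissue = tissue, hematopoietic = hema,
                        auc = auc, ic50 = ifelse(censored, NA_real_, ic50),
                        ic50_censored = censored,
                        doubling_time = pmax(doubling, 8),
                        stringsAsFactors = FALSE)

  n_rep <- 3L
  viab_sd <- 0.04   # assay replicate noise on the viability fraction
  grid <- expand.grid(replicate = seq_len(n_rep), dose_idx = seq_along(doses),
                      line_idx = seq_len(n))
  mu <- 1 / (1 + 10^(ld[grid$dose_idx] - lec50[grid$line_idx]))
  viab <- pmax(mu + rnorm(nrow(grid), 0, viab_sd), 0)
  curves <- data.frame(cell_line = cl[grid$line_idx], drug = "agent",
                       dose = doses[grid$dose_idx], replicate = grid$replicate,
                       viability = viab, stringsAsFactors = FALSE)
  curves <- curves[order(curves$cell_line, curves$dose, curves$replicate), ]
  rownames(curves) <- NULL
  list(records = records, curves = curves)
}

#' Methylome specification
#'
#' @param n_probes total CpG probes; the first
#'   `n_regions * probes_per_region` sit in promoter regions, the remainder
#'   in gene-body/noncoding/unannotated features.
#' @param n_regions promoter regions.
#' @param probes_per_region probes per promoter region.
#' @param planted_dmr_count regions hypermethylated in responders.
#' @param planted_effect delta-beta planted between responder and
#'   nonresponder class means (0 < effect < 1).
#' @param replicate_sd within-triplicate beta noise.
#' @param timing_coupling signed coefficient linking drug-A demethylation
#'   (delta-beta) to the replication-timing value.
#' @param seed integer seed.
#' @export
methylome_spec <- function(n_probes = 5000, n_regions = 500,
                           probes_per_region = 8, planted_dmr_count = 50,
                           planted_effect = 0.3, replicate_sd = 0.05,
                           timing_coupling = -0.1, seed = 1) {
  if (planted_dmr_count > n_regions) config_error("planted_dmr_count exceeds n_regions")
  if (planted_effect < 0 || planted_effect >= 1) config_error("planted_effect must be in [0, 1)")
  if (replicate_sd <= 0) config_error("replicate_sd must be > 0")
  if (n_regions * probes_per_region > n_probes) config_error("region probes exceed n_probes")
  structure(list(n_probes = as.integer(n_probes), n_regions = as.integer(n_regions),
                 probes_per_region = as.integer(probes_per_region),
                 planted_dmr_count = as.integer(planted_dmr_count),
                 planted_effect = planted_effect, replicate_sd = replicate_sd,
                 timing_coupling = timing_coupling, seed = as.integer(seed)),
            class = "methylome_spec")
}

# Target beta -> (M, U) intensities -> beta through the array formula, so the
# formula path is exercised end to end. Total intensity 4000 keeps the +100
# offset a ~2.4% shrink; gamma shape 200 keeps intensity noise well below the
# injected replicate noise.
betas_from_targets <- function(target) {
  target <- pmin(pmax(target, 0.002), 0.975)
  total <- 4000; shape <- 200
  M <- rgamma(length(target), shape = shape, rate = shape / (target * total))
  U <- rgamma(length(target), shape = shape, rate = shape / ((1 - target) * total))
  compute_beta(M, U)
}

# Sensitivity gradient used to plant class-linked effects: responders 1,
# nonresponders 0, everything else 0.5, so the responder-nonresponder
# contrast equals the planted effect exactly.
class_gradient <- function(classes) {
  g <- rep(0.5, length(classes))
  g[classes == "responder"] <- 1
  g[classes == "nonresponder"] <- 0
  g
}

#' Generate a synthetic methylome
#'
#' Produces (i) a panel beta matrix (probe x cell line) in which
#' `planted_dmr_count` promoter regions are hypermethylated in responders by
#' `planted_effect` (class gradient: responder 1, intermediate 0.5,
#' nonresponder 0); (ii) a treated-vs-DMSO triplicate experiment for two
#' drugs, where drug A demethylation is coupled to replication timing
#' (`delta-beta ~ timing_coupling * timing`) and drug B demethylates
#' uniformly and more strongly; (iii) the probe manifest, promoter region
#' map, replication-timing track and chromatin-mark tracks on one
#' pseudo-chromosome (`chrS`, probes every 500 bp, BED 0-based).
#'
#' Beta-values are generated on the intensity scale (gamma-distributed M and
#' U passed through [compute_beta()]), never directly.
#'
#' @param spec a [methylome_spec()].
#' @param panel output of [generate_panel()] (response classes are derived
#'   here with [classify_responders()], keeping the tertile split on the
#'   critical path).
#' @return list with `panel_beta`, `experiment` (`beta` matrix + `design`),
#'   `manifest`, `region_map`, `timing_track`, `mark_tracks`,
#'   `planted_regions`, `classes`.
#' @export
generate_methylome <- function(spec, panel) {
  stopifnot(inherits(spec, "methylome_spec"))
  if (!nrow(panel$records)) input_error("panel is empty")
  set.seed(spec$seed)
  records <- classify_responders(panel$records)
  classes <- as.character(records$response_class)
  g <- class_gradient(classes)
  n_lines <- nrow(records)

  n_region_probes <- spec$n_regions * spec$probes_per_region
  probe_id <- sprintf("cg%06d", seq_len(spec$n_probes))
  pos <- (seq_len(spec$n_probes) - 1L) * 500L
  region_id <- c(rep(sprintf("R%04d", seq_len(spec$n_regions)),
                     each = spec$probes_per_region),
                 rep(NA_character_, spec$n_probes - n_region_probes))
  feature <- c(sample(c("TSS1500", "CGI"), n_region_probes, replace = TRUE),
               sample(c("gene_body", "noncoding", "unannotated"),
                      spec$n_probes - n_region_probes, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2)))
  manifest <- data.frame(probe_id = probe_id, chrom = "chrS", pos = pos,
                         genomic_feature = feature, stringsAsFactors = FALSE)
  region_map <- data.frame(probe_id = probe_id[seq_len(n_region_probes)],
                           region_id = region_id[seq_len(n_region_probes)],
                           stringsAsFactors = FALSE)

  # replication timing: 5 kb tiles, signed score spanning the three classes
  tile_w <- 5000L
  axis_end <- max(pos) + 500L
  tile_starts <- seq(0L, axis_end - 1L, by = tile_w)
  timing_vals <- rnorm(length(tile_starts), 0.5, 1)
  timing_track <- data.frame(chrom = "chrS", start = tile_starts,
                             end = pmin(tile_starts + tile_w, axis_end),
                             value = timing_vals, stringsAsFactors = FALSE)
  probe_timing <- timing_vals[findInterval(pos, tile_starts)]

  # chromatin marks: random interval unions covering ~30% of the axis each
  mark_tracks <- lapply(CHROMATIN_MARKS, function(mk) {
    n_iv <- 60L
    starts <- sort(sample.int(axis_end - 2000L, n_iv))
    data.frame(chrom = "chrS", start = starts,
               end = starts + sample(500:4000, n_iv, replace = TRUE),
               label = mk, stringsAsFactors = FALSE)
  })
  names(mark_tracks) <- CHROMATIN_MARKS

  # ---- panel beta matrix (probe x line) -------------------------------
  region_base <- runif(spec$n_regions, 0.15, 0.55)
  planted_regions <- sort(sample(sprintf("R%04d", seq_len(spec$n_regions)),
                                 spec$planted_dmr_count))
  planted <- sprintf("R%04d", seq_len(spec$n_regions)) %in% planted_regions
  probe_base <- c(rep(region_base, each = spec$probes_per_region),
                  runif(spec$n_probes - n_region_probes, 0.1, 0.9))
  probe_planted <- c(rep(planted, each = spec$probes_per_region),
                     rep(FALSE, spec$n_probes - n_region_probes))
  target <- outer(probe_base, rep(1, n_lines)) +
    spec$planted_effect * outer(probe_planted, g) +
    matrix(rnorm(spec$n_probes * n_lines, 0, spec$replicate_sd),
           spec$n_probes, n_lines)
  panel_beta <- matrix(betas_from_targets(target), spec$n_probes, n_lines,
                       dimnames = list(probe_id, records$cell_line))

  # ---- treated-vs-DMSO triplicate experiment --------------------------
  base_trt <- runif(spec$n_probes, 0.45, 0.85)
  delta_a <- spec$timing_coupling * probe_timing
  delta_b <- rep(-0.15, spec$n_probes)          # uniform, stronger demethylation
  conditions <- c("DMSO", "drugA", "drugB")
  design <- expand.grid(replicate = 1:3, condition = conditions,
                        stringsAsFactors = FALSE)[, 2:1]
  design$sample <- paste0(design$condition, "_", design$replicate)
  exp_target <- vapply(seq_len(nrow(design)), function(j) {
    mu <- switch(design$condition[j],
                 DMSO = base_trt,
                 drugA = base_trt + delta_a,
                 drugB = base_trt + delta_b)
    mu + rnorm(spec$n_probes, 0, spec$replicate_sd)
  }, numeric(spec$n_probes))
  exp_beta <- matrix(betas_from_targets(exp_target), spec$n_probes, nrow(design),
                     dimnames = list(probe_id, design$sample))

  list(panel_beta = panel_beta,
       experiment = list(beta = exp_beta, design = design),
       manifest = manifest, region_map = region_map,
       timing_track = timing_track, mark_tracks = mark_tracks,
       planted_regions = planted_regions, classes = classes)
}

#' Omics specification
#'
#' @param n_genes expression genes.
#' @param planted_marker_count genes with a true NR-R expression difference
#'   (half sensitivity-, half resistance-associated).
#' @param planted_log2fc absolute log2 fold change planted in markers.
#' @param confounded_gene_count genes whose expression tracks hematopoietic
#'   lineage only (the confound the covariate must absorb).
#' @param mutation_rate_background per-gene per-line background mutation
#'   probability.
#' @param planted_mutation_or odds ratio (> 0) enriching planted resistance
#'   mutations in nonresponders.
#' @param seed integer seed.
#' @export
omics_spec <- function(n_genes = 1000, planted_marker_count = 50,
                       planted_log2fc = 1.0, confounded_gene_count = 50,
                       mutation_rate_background = 0.10,
                       planted_mutation_or = 4, seed = 1) {
  if (n_genes < 0 || planted_marker_count < 0 || confounded_gene_count < 0) {
    config_error("counts must be >= 0")
  }
  if (mutation_rate_background < 0 || mutation_rate_background > 1) {
    config_error("mutation_rate_background must be in [0,1]")
  }
  if (planted_mutation_or <= 0) config_error("planted_mutation_or must be > 0")
  if (planted_marker_count + confounded_gene_count > n_genes) {
    config_error("planted + confounded genes exceed n_genes")
  }
  structure(list(n_genes = as.integer(n_genes),
                 planted_marker_count = as.integer(planted_marker_count),
                 planted_log2fc = planted_log2fc,
                 confounded_gene_count = as.integer(confounded_gene_count),
                 mutation_rate_background = mutation_rate_background,
                 planted_mutation_or = planted_mutation_or,
                 seed = as.integer(seed)),
            class = "omics_spec")
}

#' Generate synthetic expression, mutation, and protein matrices
#'
#' Expression (log2 scale, Gaussian noise sd 0.5 around a gene-level
#' baseline): the first `planted_marker_count` genes carry a true class
#' effect of +/- `planted_log2fc` (NR - R), the next `confounded_gene_count`
#' genes track hematopoietic lineage only. Mutations are Bernoulli draws at
#' a per-line rate that rises for sensitive lines (responders carry a higher
#' burden); five planted resistance genes (`TP53`-like labels) are enriched
#' in nonresponders at `planted_mutation_or`. The protein matrix (40
#' features) plants six IC50-correlated proteins (alternating sign).
#'
#' @param spec an [omics_spec()].
#' @param panel output of [generate_panel()].
#' @return list with `expression`, `mutations`, `proteins` (feature x line
#'   matrices), plus `planted_markers`, `confounded_genes`,
#'   `planted_mutation_genes`, `classes`.
#' @export
generate_omics <- function(spec, panel) {
  stopifnot(inherits(spec, "omics_spec"))
  if (!nrow(panel$records)) input_error("panel is empty")
  set.seed(spec$seed)
  records <- classify_responders(panel$records)
  classes <- as.character(records$response_class)
  g <- class_gradient(classes)
  lin <- as.numeric(records$hematopoietic)
  n_lines <- nrow(records)
  cl <- records$cell_line

  gene_id <- sprintf("G%05d", seq_len(spec$n_genes))
  k_m <- spec$planted_marker_count; k_c <- spec$confounded_gene_count
  planted_markers <- gene_id[seq_len(k_m)]
  confounded_genes <- gene_id[k_m + seq_len(k_c)]
  baseline <- rnorm(spec$n_genes, 7, 1)
  fc <- numeric(spec$n_genes)
  if (k_m > 0) fc[seq_len(k_m)] <- spec$planted_log2fc *
      rep_len(c(1, -1), k_m)   # NR - R effect, alternating direction
  lin_fc <- numeric(spec$n_genes)
  if (k_c > 0) lin_fc[k_m + seq_len(k_c)] <- 1.0
  # class gradient: NR = 1 - g, so the NR - R contrast equals fc
  expr <- baseline + outer(fc, 1 - g) + outer(lin_fc, lin) +
    matrix(rnorm(spec$n_genes * n_lines, 0, 0.5), spec$n_genes, n_lines)
  dimnames(expr) <- list(gene_id, cl)

  # mutations: burden coupled to sensitivity (low AUC -> higher rate)
  n_mut_genes <- 200L
  mut_gene_id <- c("TP53", "RB1", "NSD1", "DNMT3A", "TET2",
                   sprintf("MG%03d", seq_len(n_mut_genes - 5L)))
  planted_mut <- mut_gene_id[1:5]
  auc_rank <- rank(records$auc) / n_lines
  rate_line <- spec$mutation_rate_background * (0.6 + 0.8 * (1 - auc_rank))
  mut <- matrix(0L, n_mut_genes, n_lines, dimnames = list(mut_gene_id, cl))
  if (spec$mutation_rate_background > 0) {
    mut[] <- rbinom(n_mut_genes * n_lines, 1,
                    rep(pmin(rate_line, 1), each = n_mut_genes))
  }
  # planted resistance mutations: odds scaled up in nonresponders; with a
  # zero background rate the planted genes are silent too (fully null world)
  p0 <- spec$mutation_rate_background
  if (p0 > 0) {
    odds0 <- p0 / (1 - p0)
    p_nr <- (odds0 * spec$planted_mutation_or) / (1 + odds0 * spec$planted_mutation_or)
    nr <- classes == "nonresponder"
    for (pg in planted_mut) {
      mut[pg, ] <- rbinom(n_lines, 1, ifelse(nr, p_nr, p0))
    }
  }

  # proteins: 40 features, six correlated with log2(IC50)
  n_prot <- 40L
  prot_id <- sprintf("P%03d", seq_len(n_prot))
  l2ic50 <- log2(ifelse(is.na(records$ic50), max(records$ic50, na.rm = TRUE),
                        records$ic50))
  z <- as.numeric(scale(l2ic50))
  loading <- numeric(n_prot)
  loading[1:6] <- 0.6 * rep_len(c(1, -1), 6)
  prot <- outer(loading, z) + matrix(rnorm(n_prot * n_lines, 0, 1), n_prot, n_lines)
  dimnames(prot) <- list(prot_id, cl)

  list(expression = expr, mutations = mut, proteins = prot,
       planted_markers = planted_markers, confounded_genes = confounded_genes,
       planted_mutation_genes = planted_mut, classes = classes)
}

#' @importFrom stats rnorm runif rgamma rbinom uniroot
NULL
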