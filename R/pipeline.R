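# End-to-end orchestration: generate -> sensitivity -> annotate -> dmc ->
# biomarkers -> synergy, from one config, with a JSON run manifest recording
# the seed, every parameter, and input/output file hashes. Stages whose
# signature (parameters + input hashes) is unchanged are skipped on rerun.

obj_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

file_md5s <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Default pipeline configuration
#'
#' All analysis thresholds default to the values used throughout the package:
#' sensitive = lowest 50% AUC, tertile responder split, DMC rule p < 0.05 with
#' nested delta-beta cutoffs {0, -0.05, -0.1, -0.2}, screen FDR 0.05,
#' replication-timing class thresholds {0, 1}.
#'
#' @param out_dir run directory.
#' @param seed master seed; generator seeds are derived from it.
#' @return nested config list.
#' @export
default_config <- function(out_dir = "hma_run", seed = 1) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = c("generate", "sensitivity", "annotate", "dmc", "biomarkers", "synergy"),
    panel = list(n_cell_lines = 300, auc_shift_hematopoietic = -0.15, noise_sd = 0.05),
    methylome = list(n_probes = 5000, n_regions = 500, probes_per_region = 8,
                     planted_dmr_count = 50, planted_effect = 0.3,
                     replicate_sd = 0.05, timing_coupling = -0.1),
    omics = list(n_genes = 1000, planted_marker_count = 50, planted_log2fc = 1,
                 confounded_gene_count = 50, mutation_rate_background = 0.1,
                 planted_mutation_or = 4),
    fdr = 0.05,
    dmc_cutoff = 0,
    n_iterations = 1000,
    synergy = list(m_a = 1, Dm_a = 100, m_b = 1.2, Dm_b = 250)
  )
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) config_error(sprintf("config file '%s' not found", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  base <- default_config()
  out <- utils::modifyList(base, config)
  if (!is.numeric(out$fdr) || out$fdr <= 0 || out$fdr >= 1) config_error("fdr must be in (0,1)")
  if (!out$dmc_cutoff %in% DMC_CUTOFFS) config_error("dmc_cutoff must be one of {0,-0.05,-0.1,-0.2}")
  if (out$n_iterations < 1) config_error("n_iterations must be >= 1")
  out
}

stage_path <- function(cfg, ...) file.path(cfg$out_dir, ...)

load_manifest <- function(cfg) {
  mf <- stage_path(cfg, "manifest.json")
  if (file.exists(mf)) jsonlite::read_json(mf, simplifyVector = TRUE) else
    list(seed = cfg$seed, stages = list())
}

save_manifest <- function(cfg, manifest) {
  jsonlite::write_json(manifest, stage_path(cfg, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

# A stage runs unless its recorded signature (parameters + md5s of its
# declared inputs) matches and all of its outputs still exist with the
# recorded hashes (so tampering with an upstream file invalidates the cache).
stage_cached <- function(manifest, name, signature) {
  st <- manifest$stages[[name]]
  if (is.null(st)) return(FALSE)
  if (!identical(st$signature, signature)) return(FALSE)
  outs <- unlist(st$outputs)
  if (!length(outs)) return(FALSE)
  current <- file_md5s(names(outs))
  identical(unname(unlist(current[names(outs)])), unname(outs))
}

run_stage <- function(cfg, manifest, name, inputs, body) {
  signature <- obj_md5(list(cfg[[name]], cfg$seed, cfg$fdr, cfg$dmc_cutoff,
                            cfg$n_iterations, file_md5s(inputs)))
  if (stage_cached(manifest, name, signature)) {
    message(sprintf("[%s] cached, skipping", name))
    return(manifest)
  }
  t0 <- Sys.time()
  outputs <- body()
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$stages[[name]] <- list(
    signature = signature,
    inputs = file_md5s(inputs),
    outputs = file_md5s(outputs),
    elapsed_sec = round(elapsed, 2),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  message(sprintf("[%s] done in %.1fs (%d output file(s))", name, elapsed, length(outputs)))
  manifest
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order inside `out_dir`,
#' writing TSV interchange files and a JSON manifest with the seed, all
#' parameters, and input/output hashes. Reruns with an identical config reuse
#' cached stage outputs; tampering with an upstream file invalidates the
#' cache of stages that consume it.
#'
#' @param config a config list (see [default_config()]) or path to a JSON
#'   config file.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- read_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- load_manifest(cfg)
  manifest$seed <- cfg$seed
  manifest$config <- cfg

  p_records  <- stage_path(cfg, "panel_records.tsv")
  p_curves   <- stage_path(cfg, "viability_curves.tsv")
  p_beta     <- stage_path(cfg, "panel_beta.tsv")
  p_expbeta  <- stage_path(cfg, "experiment_beta.tsv")
  p_design   <- stage_path(cfg, "experiment_design.tsv")
  p_manifest <- stage_path(cfg, "probe_manifest.tsv")
  p_regions  <- stage_path(cfg, "region_map.tsv")
  p_timing   <- stage_path(cfg, "timing.bed")
  p_marks    <- stage_path(cfg, "chromatin_marks.bed")
  p_mut      <- stage_path(cfg, "mutations.tsv")
  p_expr     <- stage_path(cfg, "expression.tsv")
  p_prot     <- stage_path(cfg, "proteins.tsv")

  if ("generate" %in% cfg$stages) {
    manifest <- run_stage(cfg, manifest, "generate", character(0), function() {
      pspec <- do.call(panel_spec, c(cfg$panel, list(seed = derive_seed(cfg$seed, 1))))
      panel <- generate_panel(pspec)
      mspec <- do.call(methylome_spec, c(cfg$methylome, list(seed = derive_seed(cfg$seed, 2))))
      meth <- generate_methylome(mspec, panel)
      ospec <- do.call(omics_spec, c(cfg$omics, list(seed = derive_seed(cfg$seed, 3))))
      omics <- generate_omics(ospec, panel)

      write_tsv(panel$records, p_records)
      write_tsv(panel$curves, p_curves)
      write_matrix <- function(m, path, id = "feature_id") {
        df <- data.frame(rownames(m), m, check.names = FALSE)
        names(df)[1] <- id
        write_tsv(df, path)
      }
      write_matrix(meth$panel_beta, p_beta, "probe_id")
      write_matrix(meth$experiment$beta, p_expbeta, "probe_id")
      write_tsv(meth$experiment$design, p_design)
      write_tsv(meth$manifest, p_manifest)
      write_tsv(meth$region_map, p_regions)
      data.table::fwrite(meth$timing_track, p_timing, sep = "\t", col.names = FALSE)
      data.table::fwrite(do.call(rbind, meth$mark_tracks), p_marks, sep = "\t",
                         col.names = FALSE)
      write_tsv(data.frame(region_id = meth$planted_regions),
                stage_path(cfg, "planted_regions.tsv"))
      write_matrix(omics$mutations, p_mut, "gene")
      write_matrix(omics$expression, p_expr, "gene")
      write_matrix(omics$proteins, p_prot, "protein")
      c(p_records, p_curves, p_beta, p_expbeta, p_design, p_manifest,
        p_regions, p_timing, p_marks, p_mut, p_expr, p_prot,
        stage_path(cfg, "planted_regions.tsv"))
    })
  }

  p_sens <- stage_path(cfg, "sensitivity_records.tsv")
  p_enrich <- stage_path(cfg, "tissue_enrichment.tsv")
  if ("sensitivity" %in% cfg$stages) {
    manifest <- run_stage(cfg, manifest, "sensitivity", c(p_records, p_curves), function() {
      curves <- read_tsv(p_curves)
      records <- read_tsv(p_records)
      per_line <- split(curves, curves$cell_line)
      metrics <- lapply(per_line, function(cc) {
        doses <- sort(unique(cc$dose))
        vm <- tapply(cc$viability, cc$dose, mean)[as.character(doses)]
        fit <- fit_ic50(doses, as.numeric(vm))
        data.frame(cell_line = cc$cell_line[1],
                   auc = compute_auc(doses, as.numeric(vm)),
                   ic50 = fit$ic50, ic50_censored = fit$censored)
      })
      m <- do.call(rbind, metrics)
      rec <- merge(records[, c("cell_line", "tissue", "hematopoietic", "doubling_time")],
                   m, by = "cell_line")
      rec <- flag_sensitive(rec)
      rec <- classify_responders(rec)
      write_tsv(rec, p_sens)
      enrich <- do.call(rbind, lapply(unique(rec$tissue), function(t)
        tissue_odds_ratio(rec, t)))
      write_tsv(enrich, p_enrich)
      c(p_sens, p_enrich)
    })
  }

  p_annot <- stage_path(cfg, "annotated_manifest.tsv")
  if ("annotate" %in% cfg$stages) {
    manifest <- run_stage(cfg, manifest, "annotate", c(p_manifest, p_timing, p_marks), function() {
      man <- read_tsv(p_manifest)
      marks <- read_track(p_marks, "chromatin_mark")
      timing <- read_track(p_timing, "replication_timing")
      ann <- annotate_probes(man, list(marks), timing)
      write_tsv(ann, p_annot)
      p_annot
    })
  }

  p_dmc_a <- stage_path(cfg, "dmc_drugA.tsv")
  p_dmc_b <- stage_path(cfg, "dmc_drugB.tsv")
  p_ratio <- stage_path(cfg, "demethylation_ratio.tsv")
  p_timing_prof <- stage_path(cfg, "timing_profile.json")
  if ("dmc" %in% cfg$stages) {
    manifest <- run_stage(cfg, manifest, "dmc", c(p_expbeta, p_design, p_annot), function() {
      beta <- read_beta_matrix(p_expbeta)
      design <- read_tsv(p_design)
      dmc_a <- call_dmcs(beta, design, "drugA")
      dmc_b <- call_dmcs(beta, design, "drugB")
      write_tsv(dmc_a, p_dmc_a)
      write_tsv(dmc_b, p_dmc_b)
      ann <- read_tsv(p_annot)
      ratio <- normalized_demethylation_ratio(
        dmc_a, dmc_b,
        setNames(ann$genomic_feature, ann$probe_id), cutoff = cfg$dmc_cutoff)
      write_tsv(ratio, p_ratio)
      prof <- timing_demethylation_profile(dmc_a, ann, cutoff = cfg$dmc_cutoff)
      sh <- shared_dmcs(dmc_a, dmc_b, cutoff = cfg$dmc_cutoff)
      jsonlite::write_json(list(fractions = as.list(prof$fractions), r = prof$r,
                                p_value = prof$p_value, shared = sh),
                           p_timing_prof, auto_unbox = TRUE, digits = NA)
      c(p_dmc_a, p_dmc_b, p_ratio, p_timing_prof)
    })
  }

  p_de <- stage_path(cfg, "differential_expression.tsv")
  p_ma <- stage_path(cfg, "mutation_association.tsv")
  p_dmr <- stage_path(cfg, "dmr_screen.tsv")
  p_score <- stage_path(cfg, "region_set_score.json")
  if ("biomarkers" %in% cfg$stages) {
    manifest <- run_stage(cfg, manifest, "biomarkers",
                          c(p_sens, p_expr, p_mut, p_beta, p_regions), function() {
      rec <- read_tsv(p_sens)
      expr <- read_beta_matrix(p_expr)
      expr <- expr[, rec$cell_line, drop = FALSE]
      de <- differential_expression(expr, rec$response_class, rec$hematopoietic)
      write_tsv(de, p_de)
      mut <- read_beta_matrix(p_mut)[, rec$cell_line, drop = FALSE]
      ma <- mutation_association(mut, rec$response_class, rec$hematopoietic)
      write_tsv(ma, p_ma)
      beta <- read_beta_matrix(p_beta)[, rec$cell_line, drop = FALSE]
      rmap <- read_tsv(p_regions)
      rmeans <- region_means(beta, rmap)
      dmr <- differential_methylation_regions(rmeans, rec$response_class, rec$hematopoietic)
      write_tsv(dmr, p_dmr)
      hits <- dmr$feature_id[dmr$p_adjusted < cfg$fdr & dmr$coefficient < 0]
      ic50 <- ifelse(rec$ic50_censored, NA, rec$ic50)
      score <- NULL
      if (length(hits) >= 2) {
        rss <- region_set_score(hits, rmeans, ic50)
        pn <- permutation_null(length(hits), rownames(rmeans), rmeans, ic50,
                               rss$r_observed, n_iterations = cfg$n_iterations,
                               seed = derive_seed(cfg$seed, 7))
        score <- list(n_regions = length(hits), r_observed = rss$r_observed,
                      p_pearson = rss$p_value, empirical_p = pn$empirical_p,
                      n_iterations = pn$n_iterations,
                      universe_size = pn$universe_size)
      }
      jsonlite::write_json(score %||% list(note = "fewer than 2 significant regions"),
                           p_score, auto_unbox = TRUE, digits = NA)
      c(p_de, p_ma, p_dmr, p_score)
    })
  }

  p_ci <- stage_path(cfg, "combination_index.tsv")
  if ("synergy" %in% cfg$stages) {
    manifest <- run_stage(cfg, manifest, "synergy", character(0), function() {
      sy <- cfg$synergy
      set.seed(derive_seed(cfg$seed, 11))
      doses <- function(Dm) Dm * 2^seq(-3, 3)
      me_fa <- function(d, m, Dm) (d / Dm)^m / (1 + (d / Dm)^m)
      da <- doses(sy$Dm_a); db <- doses(sy$Dm_b)
      fa_a <- pmin(pmax(me_fa(da, sy$m_a, sy$Dm_a) + rnorm(length(da), 0, 0.02), 0.001), 0.999)
      fa_b <- pmin(pmax(me_fa(db, sy$m_b, sy$Dm_b) + rnorm(length(db), 0, 0.02), 0.001), 0.999)
      fit_a <- fit_median_effect(da, fa_a)
      fit_b <- fit_median_effect(db, fa_b)
      grid_a <- da[2:6]; grid_b <- db[2:6]
      # additive reference surface from the two fitted models
      fa_mat <- outer(grid_a, grid_b, function(x, y) {
        vapply(seq_along(x), function(i) {
          f <- function(fa) x[i] / dose_for_effect(fit_a, fa) +
            y[i] / dose_for_effect(fit_b, fa) - 1
          uniroot(f, c(1e-6, 1 - 1e-6))$root
        }, numeric(1))
      })
      sm <- score_matrix(grid_a, grid_b, fa_mat, fit_a, fit_b)
      out <- data.frame(dose_a = rep(grid_a, times = length(grid_b)),
                        dose_b = rep(grid_b, each = length(grid_a)),
                        fa = as.vector(fa_mat), ci = as.vector(sm$ci),
                        unscored = as.vector(sm$unscored))
      write_tsv(out, p_ci)
      p_ci
    })
  }

  save_manifest(cfg, manifest)
  invisible(manifest)
}

# Feature x sample TSV with the id in column 1 -> numeric matrix.
read_beta_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}
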