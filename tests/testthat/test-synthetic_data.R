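test_that("spec constructors validate their invariants", {
  expect_error(panel_spec(tissue_proportions = c(blood = 0.5, lung = 0.4)),
               class = "hmakit_config_error")
  expect_error(panel_spec(n_cell_lines = 4), class = "hmakit_config_error")
  expect_error(panel_spec(noise_sd = 0), class = "hmakit_config_error")
  expect_error(methylome_spec(n_regions = 10, planted_dmr_count = 11),
               class = "hmakit_config_error")
  expect_error(methylome_spec(planted_effect = 1.2), class = "hmakit_config_error")
  expect_error(omics_spec(mutation_rate_background = 1.5), class = "hmakit_config_error")
  expect_error(omics_spec(planted_mutation_or = 0), class = "hmakit_config_error")
})

test_that("identical spec + seed reproduces outputs exactly", {
  s <- panel_spec(n_cell_lines = 40, seed = 99)
  p1 <- generate_panel(s); p2 <- generate_panel(s)
  expect_identical(p1, p2)
  ms <- methylome_spec(n_probes = 800, n_regions = 80, probes_per_region = 8,
                       planted_dmr_count = 10, seed = 5)
  expect_identical(generate_methylome(ms, p1), generate_methylome(ms, p1))
  os <- omics_spec(n_genes = 100, seed = 5)
  expect_identical(generate_omics(os, p1), generate_omics(os, p1))
  # different seed differs
  expect_false(identical(p1, generate_panel(panel_spec(n_cell_lines = 40, seed = 100))))
})

test_that("planted AUC shift lowers hematopoietic AUC and survives the 2x2", {
  p <- generate_panel(panel_spec(n_cell_lines = 300, auc_shift_hematopoietic = -0.15,
                                 noise_sd = 0.05, seed = 7))
  r <- p$records
  expect_lt(mean(r$auc[r$hematopoietic]), mean(r$auc[!r$hematopoietic]))
  expect_true(all(p$curves$viability >= 0))
  expect_true(all(r$auc >= 0 & r$auc <= 1))
  # downstream OR oracle: 2x2 formula on the flagged table
  fl <- flag_sensitive(r)
  a <- sum(fl$sensitive & fl$hematopoietic); b <- sum(!fl$sensitive & fl$hematopoietic)
  c_ <- sum(fl$sensitive & !fl$hematopoietic); d <- sum(!fl$sensitive & !fl$hematopoietic)
  k <- if (any(c(a, b, c_, d) == 0)) 0.5 else 0  # Haldane, matching the implementation
  or_oracle <- ((a + k) * (d + k)) / ((b + k) * (c_ + k))
  expect_gt(or_oracle, 1)
  expect_equal(tissue_odds_ratio(fl, "blood")$odds_ratio, or_oracle)
})

test_that("generated curves reproduce their planted AUC through compute_auc", {
  p <- generate_panel(panel_spec(n_cell_lines = 20, seed = 31))
  for (cl in p$records$cell_line[1:10]) {
    cc <- p$curves[p$curves$cell_line == cl, ]
    doses <- sort(unique(cc$dose))
    vm <- as.numeric(tapply(cc$viability, cc$dose, mean)[as.character(doses)])
    expect_equal(compute_auc(doses, vm), p$records$auc[p$records$cell_line == cl],
                 tolerance = 0.05)
  }
})

test_that("methylome generator plants DMRs on the beta scale within [0,1)", {
  p <- small_panel(seed = 4, n = 90)
  m <- generate_methylome(methylome_spec(n_probes = 1600, n_regions = 200,
                                         probes_per_region = 8,
                                         planted_dmr_count = 20, seed = 2), p)
  expect_true(all(m$panel_beta >= 0 & m$panel_beta < 1))
  expect_true(all(m$experiment$beta >= 0 & m$experiment$beta < 1))
  rec <- classify_responders(p$records)
  rmeans <- region_means(m$panel_beta, m$region_map)
  rmean_cls <- function(regions, cls) {
    mean(rmeans[regions, rec$response_class == cls, drop = FALSE])
  }
  gap <- rmean_cls(m$planted_regions, "responder") -
    rmean_cls(m$planted_regions, "nonresponder")
  expect_equal(gap, 0.3 * 4000 / 4100, tolerance = 0.1)  # intensity-offset shrink
  # unplanted regions show no class gap beyond noise
  others <- setdiff(rownames(rmeans), m$planted_regions)
  gap0 <- rmean_cls(others, "responder") - rmean_cls(others, "nonresponder")
  expect_lt(abs(gap0), 0.02)
})

test_that("null methylome (no planted effect) leaves classes exchangeable", {
  p <- small_panel(seed = 5, n = 90)
  m <- generate_methylome(methylome_spec(n_probes = 800, n_regions = 100,
                                         probes_per_region = 8,
                                         planted_effect = 0, timing_coupling = 0,
                                         seed = 3), p)
  rec <- classify_responders(p$records)
  rmeans <- region_means(m$panel_beta, m$region_map)
  dmr <- differential_methylation_regions(rmeans, rec$response_class, rec$hematopoietic)
  # raw p roughly uniform: about 5% below 0.05
  expect_lt(abs(mean(dmr$p_value < 0.05) - 0.05), 0.06)
  expect_lte(sum(dmr$p_adjusted < 0.05), 1)
})

test_that("timing coupling sign propagates to generated delta-beta", {
  p <- small_panel(seed = 6, n = 30)
  m <- generate_methylome(methylome_spec(n_probes = 2000, n_regions = 200,
                                         probes_per_region = 8,
                                         timing_coupling = -0.1, seed = 8), p)
  dmc <- call_dmcs(m$experiment$beta, m$experiment$design, "drugA")
  ann <- annotate_probes(m$manifest, timing_track = m$timing_track)
  tv <- ann$timing_value[match(dmc$probe_id, ann$probe_id)]
  expect_lt(cor(dmc$delta_beta, tv, use = "complete.obs"), -0.5)
})

test_that("omics generator plants markers, confounds, and mutations as specified", {
  p <- small_panel(seed = 9, n = 120)
  o <- generate_omics(omics_spec(n_genes = 300, planted_marker_count = 20,
                                 planted_log2fc = 1, confounded_gene_count = 20,
                                 seed = 12), p)
  rec <- classify_responders(p$records)
  de <- differential_expression(o$expression, rec$response_class, rec$hematopoietic)
  hits <- de$feature_id[de$p_adjusted < 0.05]
  expect_gte(length(intersect(hits, o$planted_markers)), 18)
  expect_equal(length(intersect(hits, o$confounded_genes)), 0)
  # planted marker coefficients recover +/- planted_log2fc
  est <- de$coefficient[match(o$planted_markers, de$feature_id)]
  expect_equal(mean(abs(est)), 1, tolerance = 0.15)
  # planted resistance mutations enriched in nonresponders
  ma <- mutation_association(o$mutations, rec$response_class, rec$hematopoietic)
  planted <- ma[ma$feature_id %in% o$planted_mutation_genes, ]
  expect_gt(mean(planted$odds_ratio), 1.5)
  # empty matrix under zero background rate
  o0 <- generate_omics(omics_spec(n_genes = 50, planted_marker_count = 0,
                                  confounded_gene_count = 0,
                                  mutation_rate_background = 0, seed = 1), p)
  expect_equal(sum(o0$mutations), 0)
})

test_that("fully null omics keeps the raw type-I error near 5%", {
  fracs <- vapply(1:3, function(s) {
    p <- generate_panel(panel_spec(n_cell_lines = 100, seed = s + 400))
    o <- generate_omics(omics_spec(n_genes = 500, planted_marker_count = 0,
                                   planted_log2fc = 0, confounded_gene_count = 0,
                                   seed = s), p)
    rec <- classify_responders(p$records)
    de <- differential_expression(o$expression, rec$response_class, rec$hematopoietic)
    mean(de$p_value < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
})
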