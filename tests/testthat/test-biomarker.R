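# Oracle for the covariate-adjusted screens: per-feature normal-equations fit.
ols_oracle <- function(y, group, lineage) {
  X <- cbind(1, group, lineage)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - 3
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * solve(XtX)[2, 2])
  t <- beta[2] / se
  list(coef = beta[2], p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

make_classes <- function(n_r, n_nr) {
  factor(rep(c("responder", "nonresponder"), c(n_r, n_nr)),
         levels = c("responder", "intermediate", "nonresponder", "unclassified"))
}

test_that("differential_expression recovers exact planted effects", {
  classes <- make_classes(5, 5)
  lineage <- rep(c(TRUE, FALSE), 5)
  nr <- classes == "nonresponder"
  expr <- rbind(g1 = 2 + 1.0 * as.numeric(nr),          # exact class effect
                g2 = rnorm(10),
                g3 = rep(3, 10))                        # constant gene
  res <- differential_expression(expr, classes, lineage)
  r1 <- res[res$feature_id == "g1", ]
  expect_equal(r1$coefficient, 1.0)
  expect_lt(r1$p_value, 1e-12)
  expect_equal(r1$direction, "resistance_associated")
  r3 <- res[res$feature_id == "g3", ]
  expect_true(r3$constant_flag)
  expect_equal(r3$p_value, 1)
  expect_error(differential_expression(expr[, 1:4], classes[1:4], lineage[1:4]),
               class = "hmakit_input_error")
})

test_that("screen coefficients match the normal-equations oracle (n <= 10)", {
  set.seed(17)
  classes <- make_classes(5, 5)
  lineage <- c(1, 1, 0, 0, 1, 0, 1, 0, 0, 1)
  grp <- as.numeric(classes == "nonresponder")
  expr <- matrix(rnorm(80), nrow = 8,
                 dimnames = list(paste0("g", 1:8), NULL))
  expr[2, ] <- expr[2, ] + 0.8 * lineage          # lineage-confounded gene
  res <- differential_expression(expr, classes, lineage)
  for (g in rownames(expr)) {
    o <- ols_oracle(expr[g, ], grp, lineage)
    i <- res$feature_id == g
    expect_equal(res$coefficient[i], unname(o$coef), tolerance = 1e-10)
    expect_equal(res$p_value[i], unname(o$p), tolerance = 1e-10)
  }
})

test_that("lineage-only genes get near-zero adjusted group coefficients", {
  set.seed(23)
  # lineage balanced across classes so confounding is orthogonal on average
  classes <- make_classes(20, 20)
  lineage <- rep(c(1, 0), 20)
  expr <- matrix(rnorm(30 * 40, sd = 0.3), nrow = 30) + outer(rep(1, 30), lineage)
  rownames(expr) <- paste0("g", 1:30)
  res <- differential_expression(expr, classes, lineage)
  # each coefficient has se ~ 0.3*sqrt(2/20); mean of 30 ~ N(0, 0.017)
  expect_lt(abs(mean(res$coefficient)), 3 * 0.3 * sqrt(2 / 20) / sqrt(30))
  expect_equal(sum(res$p_adjusted < 0.05), 0)
})

test_that("BH adjustment is monotone and order-invariant", {
  set.seed(31)
  classes <- make_classes(5, 5)
  lineage <- rep(0:1, 5)
  expr <- matrix(rnorm(200), nrow = 20, dimnames = list(paste0("g", 1:20), NULL))
  res <- differential_expression(expr, classes, lineage)
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(all(diff(res$p_adjusted[order(res$p_value)]) >= -1e-12))
  perm <- sample(nrow(expr))
  res2 <- differential_expression(expr[perm, ], classes, lineage)
  expect_equal(res2$p_adjusted[match(res$feature_id, res2$feature_id)],
               res$p_adjusted)
})

test_that("filter_mutations applies the whitelist contract", {
  m <- matrix(0L, 5, 4, dimnames = list(c("TP53", "RB1", "KRAS", "EGFR", "BRAF"), NULL))
  expect_equal(rownames(filter_mutations(m, c("TP53", "RB1"))), c("TP53", "RB1"))
  expect_warning(out <- filter_mutations(m, NULL), "whitelist")
  expect_identical(out, m)
  expect_error(filter_mutations(m, c("MYC")), class = "hmakit_input_error")
})

test_that("mutation_association matches the 2x2 oracle and handles separation", {
  classes <- make_classes(10, 10)
  lineage <- rep(c(0, 1), 10)
  # gene mutated in 8/10 NR and 2/10 R -> 2x2 OR = (8*8)/(2*2) = 16
  nr <- classes == "nonresponder"
  mut <- matrix(0L, 3, 20, dimnames = list(c("gA", "gB", "gC"), NULL))
  mut["gA", which(nr)[1:8]] <- 1L
  mut["gA", which(!nr)[1:2]] <- 1L
  mut["gB", ] <- rep(c(0L, 1L), 10)              # identical frequency both classes
  mut["gC", which(nr)[1:5]] <- 1L                # NR-only: separation
  res <- mutation_association(mut, classes, lineage)
  a <- res[res$feature_id == "gA", ]
  expect_equal(a$odds_ratio, 16, tolerance = 0.15)
  expect_gt(a$coefficient, 0)                    # skews toward nonresponders
  b <- res[res$feature_id == "gB", ]
  expect_equal(b$odds_ratio, 1, tolerance = 0.1)
  expect_gt(b$p_value, 0.9)
  c_ <- res[res$feature_id == "gC", ]
  expect_true(c_$fallback_flag)
  expect_true(is.finite(c_$odds_ratio) && c_$odds_ratio > 1)
  # singleton mutations are skipped
  mut2 <- rbind(mut, gD = c(1L, rep(0L, 19)))
  expect_false("gD" %in% mutation_association(mut2, classes, lineage)$feature_id)
})

test_that("mutation_burden counts and transforms", {
  m <- matrix(c(0, 0, 0, 1, 1, 1, 1, 1, 1, 1, 0, 1), nrow = 4,
              dimnames = list(NULL, c("c1", "c2", "c3")))
  b <- mutation_burden(m)
  expect_equal(unname(b["c1"]), 1)
  expect_equal(sum(b), sum(m))
  m7 <- matrix(c(rep(1, 7), 0), nrow = 8, dimnames = list(NULL, "c1"))
  expect_equal(unname(mutation_burden(m7, "log2")), 3)  # log2(7 + 1)
  expect_equal(unname(mutation_burden(m7 * 0, "log2")), 0)
  expect_error(mutation_burden(m * 2), class = "hmakit_input_error")
})

test_that("DMR screen recovers planted regions and stays null under the null", {
  p <- small_panel(seed = 6, n = 120)
  m <- generate_methylome(methylome_spec(n_probes = 1600, n_regions = 200,
                                         probes_per_region = 8,
                                         planted_dmr_count = 20, seed = 13), p)
  rec <- classify_responders(p$records)
  rmeans <- region_means(m$panel_beta, m$region_map)
  dmr <- differential_methylation_regions(rmeans, rec$response_class, rec$hematopoietic)
  hits <- dmr$feature_id[dmr$p_adjusted < 0.05 & dmr$coefficient < 0]
  expect_gte(length(intersect(hits, m$planted_regions)), 16)  # >= 80%
  # null world: no planted effect -> no discoveries at FDR 0.05
  m0 <- generate_methylome(methylome_spec(n_probes = 1600, n_regions = 200,
                                          probes_per_region = 8,
                                          planted_effect = 0, seed = 14), p)
  rmeans0 <- region_means(m0$panel_beta, m0$region_map)
  dmr0 <- differential_methylation_regions(rmeans0, rec$response_class, rec$hematopoietic)
  expect_lte(sum(dmr0$p_adjusted < 0.05), 1)
})

test_that("region_set_score reduces correctly and propagates planted signs", {
  rm_ <- rbind(R1 = c(0.8, 0.6, 0.4, 0.2, 0.55),
               R2 = c(0.7, 0.5, 0.35, 0.25, 0.5))
  colnames(rm_) <- paste0("c", 1:5)
  ic50 <- 2^c(1, 2, 3, 4, 2.5)
  s1 <- region_set_score("R1", rm_, ic50)
  expect_equal(s1$r_observed, cor(rm_["R1", ], log2(ic50)))
  # exact anti-monotone set -> r = -1
  rm2 <- rbind(Rx = -log2(ic50) / 10 + 0.5)
  colnames(rm2) <- paste0("c", 1:5)
  expect_equal(region_set_score("Rx", rm2, ic50)$r_observed, -1)
  expect_error(region_set_score(character(0), rm_, ic50), class = "hmakit_input_error")
  expect_error(region_set_score("R9", rm_, ic50), class = "hmakit_input_error")
  # censored lines excluded with a count
  ic50c <- ic50; ic50c[1] <- NA
  expect_equal(region_set_score("R1", rm_, ic50c)$n_excluded, 1)
})

test_that("permutation_null implements the add-one estimator", {
  set.seed(50)
  rm_ <- matrix(runif(40 * 10), 40, 10,
                dimnames = list(sprintf("R%02d", 1:40), paste0("c", 1:10)))
  ic50 <- 2^runif(10, 0, 5)
  # |r_observed| = 1 beats every achievable null -> p = 1/(n+1)
  pn <- permutation_null(5, rownames(rm_), rm_, ic50, r_observed = 1,
                         n_iterations = 999, seed = 3)
  expect_equal(pn$empirical_p, 1 / 1000)
  # r_observed = 0 loses to everything -> p = 1
  pn0 <- permutation_null(5, rownames(rm_), rm_, ic50, r_observed = 0,
                          n_iterations = 1, seed = 3)
  expect_equal(pn0$empirical_p, 1)
  expect_error(permutation_null(100, rownames(rm_), rm_, ic50, 0.5),
               class = "hmakit_input_error")
  # determinism under a fixed seed
  pn1 <- permutation_null(5, rownames(rm_), rm_, ic50, 0.4, 200, seed = 11)
  pn2 <- permutation_null(5, rownames(rm_), rm_, ic50, 0.4, 200, seed = 11)
  expect_identical(pn1$r_null, pn2$r_null)
  expect_gt(pn1$empirical_p, 0)
})
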