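# Follow-up GLMs: LD pruning, variant driver scan, single-variant
# interaction and the exposure trend OR.

test_that("pruning drops duplicates and keeps uncorrelated variants", {
  set.seed(1)
  a <- rbinom(200, 2, 0.3); b <- rbinom(200, 2, 0.4)
  G <- cbind(v1 = a, v2 = a, v3 = b)
  expect_identical(prune_variants(G), c("v1", "v3"))
  G2 <- cbind(x = rbinom(500, 2, 0.3), y = rbinom(500, 2, 0.3),
              z = rbinom(500, 2, 0.3))
  expect_identical(prune_variants(G2), c("x", "y", "z"))
  # monomorphic variants are uninformative and removed
  G3 <- cbind(v1 = a, mono = rep(1, 200))
  expect_identical(prune_variants(G3), "v1")
})

test_that("pruning matches an exhaustive oracle on an AR(1) block", {
  cfg <- sim_config(n_cases = 10, n_controls = 10,
                    blocks = list(list(n_variants = 10,
                                       maf_range = c(0.3, 0.3),
                                       rho = 0.998)),
                    genes = data.frame(gene_id = "G1", block = 1,
                                       n_nonzero_weights = 1,
                                       target_r2 = 0.1),
                    n_population = 5000, seed = 44)
  g <- simulate_genotypes(cfg)
  G <- g$dosage
  kept <- prune_variants(G, positions = g$variants$pos, r2_max = 0.9)
  # independently coded greedy pass over position order
  oracle <- character(0)
  for (j in order(g$variants$pos)) {
    if (sd(G[, j]) < 1e-12) next
    r2 <- vapply(oracle, function(k) cor(G[, j], G[, k])^2, numeric(1))
    if (all(r2 < 0.9)) oracle <- c(oracle, colnames(G)[j])
  }
  expect_setequal(kept, oracle)
  expect_lt(length(kept), 10)        # high LD must remove something
  # determinism
  expect_identical(kept, prune_variants(G, positions = g$variants$pos))
})

test_that("driver scan on one variant equals single_variant_interaction", {
  cfg <- null_scan_config(1, seed = 52, n_cases = 500, n_controls = 500,
                          n_variants = 1, n_weights = 1)
  sc <- run_scan(cfg)
  tab <- sc$table
  G <- sc$grex$aligned[[1]]$dosage
  d1 <- variant_driver_scan(tab, G)
  d2 <- single_variant_interaction(tab, G[, 1],
                                   variant_id = colnames(G)[1])
  expect_equal(d1$ratio_or, d2$ratio_or, tolerance = 1e-10)
  expect_equal(d1$p_int, d2$p_int, tolerance = 1e-10)
})

test_that("constant exposure or dosage is rejected", {
  cfg <- null_scan_config(1, seed = 53, n_cases = 200, n_controls = 200)
  sc <- run_scan(cfg)
  g <- sc$grex$aligned[[1]]$dosage[, 1]
  expect_error(single_variant_interaction(sc$table, g,
                                          e = rep(1, nrow(sc$table))),
               "constant")
  expect_error(single_variant_interaction(sc$table,
                                          rep(2, nrow(sc$table))),
               "constant")
})

test_that("stratified ORs are null-calibrated and reference-free in Q1", {
  pints <- NULL
  reps <- 40
  for (r in seq_len(reps)) {
    cfg <- null_scan_config(1, seed = 1200 + r, n_cases = 600,
                            n_controls = 600, beta_grex = 0.1)
    sc <- run_scan(cfg)
    so <- stratified_expression_or(sc$table, sc$grex$grex[, 1], "G1")
    expect_true(is.na(so$p_int[1]))
    expect_true(all(so$ci_low <= so$or & so$or <= so$ci_high))
    pints <- c(pints, so$p_int[2:4])
  }
  # identical true effect in every quartile: interaction p-values uniform
  expect_uniform_ks(pints)
})

test_that("stratified ORs cover a null expression effect", {
  hit <- 0
  reps <- 40
  for (r in seq_len(reps)) {
    cfg <- null_scan_config(1, seed = 1400 + r, n_cases = 600,
                            n_controls = 600, beta_grex = 0)
    sc <- run_scan(cfg)
    so <- stratified_expression_or(sc$table, sc$grex$grex[, 1], "G1")
    hit <- hit + all(so$ci_low <= 1 & 1 <= so$ci_high)
  }
  # four simultaneous 95% intervals around a true null
  expect_gte(hit / reps, 0.7)
})

test_that("rising true ORs across quartiles are recovered as monotone", {
  mono <- 0
  reps <- 25
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_cases = 6000, n_controls = 6000, n_studies = 2,
                      blocks = list(list(n_variants = 6,
                                         maf_range = c(0.1, 0.4),
                                         rho = 0.4)),
                      genes = data.frame(gene_id = "G1", block = 1,
                                         n_nonzero_weights = 4,
                                         target_r2 = 0.17),
                      effects = list(intercept = qlogis(0.3),
                                     beta_age = 0.1, beta_sex = 0.1,
                                     beta_e = -0.09,
                                     beta_grex = log(1.1),
                                     gamma_fixed = log(1.45 / 1.1) / 3),
                      seed = 1600 + r)
    sc <- run_scan(cfg)
    so <- stratified_expression_or(sc$table, sc$grex$grex[, 1], "G1")
    mono <- mono + all(diff(so$or) > 0)
  }
  expect_gte(mono / reps, 0.6)
})

test_that("exposure trend OR covers the null and ignores noise covariates", {
  hit <- 0
  reps <- 30
  for (r in seq_len(reps)) {
    cfg <- null_scan_config(1, seed = 1800 + r, n_cases = 600,
                            n_controls = 600)
    sc <- run_scan(cfg)
    tr <- exposure_trend_or(sc$table)
    hit <- hit + (tr$ci_low <= 1 & 1 <= tr$ci_high)
  }
  expect_gte(hit / reps, 0.8)
  # adding an uncorrelated covariate moves the OR by < 2%
  cfg <- null_scan_config(1, seed = 1900, n_cases = 2000,
                          n_controls = 2000)
  sc <- run_scan(cfg)
  t1 <- exposure_trend_or(sc$table)
  set.seed(99)
  t2 <- exposure_trend_or(sc$table,
                          extra = cbind(noise = rnorm(nrow(sc$table))))
  expect_lt(abs(t2$or / t1$or - 1), 0.02)
})

test_that("a generated protective trend near OR 0.91 is recovered", {
  logors <- numeric(20)
  for (r in seq_len(20)) {
    cfg <- sim_config(n_cases = 5000, n_controls = 5000, n_studies = 2,
                      blocks = list(list(n_variants = 2,
                                         maf_range = c(0.2, 0.4),
                                         rho = 0.3)),
                      genes = data.frame(gene_id = "G1", block = 1,
                                         n_nonzero_weights = 1,
                                         target_r2 = 0.1),
                      effects = list(intercept = qlogis(0.3),
                                     beta_age = 0.1, beta_sex = 0.1,
                                     beta_e = log(0.91)),
                      seed = 2100 + r)
    sc <- run_scan(cfg)
    logors[r] <- log(exposure_trend_or(sc$table)$or)
  }
  pooled <- exp(mean(logors))
  expect_gte(pooled, 0.89)
  expect_lte(pooled, 0.93)
})

test_that("an injected variant-level driver attains the smallest p", {
  wins <- 0
  reps <- 15
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_cases = 3000, n_controls = 3000, n_studies = 2,
                      blocks = list(list(n_variants = 5,
                                         maf_range = c(0.2, 0.4),
                                         rho = 0.2)),
                      genes = data.frame(gene_id = "G1", block = 1,
                                         n_nonzero_weights = 3,
                                         target_r2 = 0.2),
                      effects = list(intercept = qlogis(0.3),
                                     beta_e = -0.05),
                      seed = 2300 + r)
    b <- simulate_cohort(cfg)
    tab <- build_analysis_table(b$cohort)
    idx <- match(tab$subject_id, b$cohort$subject_id)
    G <- b$genotypes$dosage[idx, , drop = FALSE]
    e <- tab$folate_q - 1
    # inject a variant-level interaction directly into the outcome
    eta <- qlogis(mean(tab$status)) + log(0.8) * G[, 3] * e
    tab$status <- rbinom(nrow(tab), 1, plogis(eta))
    if (length(unique(tab$status)) < 2) next
    kept <- prune_variants(G, positions = b$genotypes$variants$pos)
    dr <- variant_driver_scan(tab, G[, kept, drop = FALSE])
    wins <- wins + (dr$variant_id[which.min(dr$p_int)] == colnames(G)[3])
  }
  expect_gte(wins / reps, 0.7)
})
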