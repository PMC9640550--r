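# The synthetic cohort generator: determinism, Hardy-Weinberg
# marginals, LD structure against an orthant-probability oracle,
# weight-set prediction R2, exposure marginals, and the disease model.

test_that("identical configs give bit-identical bundles", {
  cfg <- null_scan_config(3, seed = 11, n_cases = 150, n_controls = 150)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1$genotypes$dosage, b2$genotypes$dosage)
  expect_identical(b1$cohort, b2$cohort)
  expect_identical(b1$truth$realized_r2, b2$truth$realized_r2)
})

test_that("genotypes are in HWE at their MAF", {
  cfg <- sim_config(n_cases = 10, n_controls = 10,
                    blocks = list(list(n_variants = 1,
                                       maf_range = c(0.5, 0.5), rho = 0)),
                    genes = data.frame(gene_id = "G1", block = 1,
                                       n_nonzero_weights = 1,
                                       target_r2 = 0.1),
                    n_population = 100000, seed = 3)
  g <- simulate_genotypes(cfg)
  freq <- tabulate(g$dosage[, 1] + 1, 3) / 1e5
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 1e5)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))
})

test_that("HWE chi-square rejections across 100 variants are nominal", {
  cfg <- sim_config(n_cases = 10, n_controls = 10,
                    blocks = list(list(n_variants = 100,
                                       maf_range = c(0.1, 0.45), rho = 0)),
                    genes = data.frame(gene_id = "G1", block = 1,
                                       n_nonzero_weights = 1,
                                       target_r2 = 0.1),
                    n_population = 20000, seed = 17)
  g <- simulate_genotypes(cfg)
  rej <- vapply(seq_len(100), function(j) {
    d <- g$dosage[, j]
    n <- length(d)
    p <- mean(d) / 2
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(d + 1, 3)
    x2 <- sum((obs - expd)^2 / expd)
    pchisq(x2, df = 1, lower.tail = FALSE) < 0.05
  }, logical(1))
  # Binomial(100, 0.05): central 99.9% range
  expect_gte(sum(rej), qbinom(5e-4, 100, 0.05))
  expect_lte(sum(rej), qbinom(1 - 5e-4, 100, 0.05))
})

test_that("within-block dosage correlation matches the latent-threshold oracle", {
  skip_if_not_installed("mvtnorm")
  maf <- 0.3; rho <- 0.8
  cfg <- sim_config(n_cases = 10, n_controls = 10,
                    blocks = list(list(n_variants = 2,
                                       maf_range = c(maf, maf), rho = rho)),
                    genes = data.frame(gene_id = "G1", block = 1,
                                       n_nonzero_weights = 1,
                                       target_r2 = 0.1),
                    n_population = 20000, seed = 5)
  g <- simulate_genotypes(cfg)
  # Brute-force oracle: E[d1 d2] from bivariate-normal rectangle
  # probabilities of the latent thresholds.
  cuts <- qnorm(c((1 - maf)^2, (1 - maf)^2 + 2 * maf * (1 - maf)))
  bounds <- list(c(-Inf, cuts[1]), c(cuts[1], cuts[2]), c(cuts[2], Inf))
  sigma <- matrix(c(1, rho, rho, 1), 2)
  m1 <- maf * 2
  e12 <- 0
  for (i in 1:3) for (j in 1:3) {
    pr <- mvtnorm::pmvnorm(lower = c(bounds[[i]][1], bounds[[j]][1]),
                           upper = c(bounds[[i]][2], bounds[[j]][2]),
                           sigma = sigma)
    e12 <- e12 + (i - 1) * (j - 1) * as.numeric(pr)
  }
  v <- 2 * maf * (1 - maf)   # HWE dosage variance
  implied <- (e12 - m1^2) / v
  expect_lt(abs(cor(g$dosage[, 1], g$dosage[, 2]) - implied), 0.05)
})

test_that("weight sets respect sparsity and realize the target R2", {
  expect_error(sim_config(genes = data.frame(gene_id = "G1", block = 1,
                                             n_nonzero_weights = 2,
                                             target_r2 = 0)),
               "target_r2")
  expect_error(sim_config(genes = data.frame(gene_id = "G1", block = 1,
                                             n_nonzero_weights = 2,
                                             target_r2 = 1)),
               "target_r2")
  cfg <- sim_config(n_cases = 10, n_controls = 10,
                    blocks = list(list(n_variants = 10,
                                       maf_range = c(0.1, 0.4), rho = 0.3)),
                    genes = data.frame(gene_id = c("G1", "G2"),
                                       block = 1,
                                       n_nonzero_weights = c(1, 5),
                                       target_r2 = c(0.1, 0.17)),
                    n_population = 20000, seed = 4)
  g <- simulate_genotypes(cfg)
  w <- simulate_weightsets(g, cfg)
  expect_identical(nrow(w$weightsets[["G1"]]$variants), 1L)
  expect_true(all(w$weightsets[["G1"]]$variants$weight != 0))
  expect_gte(w$realized_r2[["G2"]], 0.12)
  expect_lte(w$realized_r2[["G2"]], 0.22)
  # the latent trait realizes exactly the recorded R2 against the score
  al <- align_variants(g, w$weightsets[["G2"]])
  gx <- predict_expression(al$dosage, al$weights)
  expect_equal(cor(gx$raw, w$expression[, "G2"])^2,
               unname(w$realized_r2[["G2"]]), tolerance = 1e-10)
})

test_that("exposure marginals follow the configuration", {
  base <- list(log_mean = log(300), log_sd = 0.5, supplement_dose = 400)
  cfg0 <- sim_config(n_cases = 10, n_controls = 10,
                     exposure = c(base, supplement_user_prob = 0),
                     n_population = 2000, seed = 8)
  ph0 <- simulate_exposure_covariates(cfg0)
  expect_true(all(ph0$supp_folate_mcg == 0))
  cfg1 <- sim_config(n_cases = 10, n_controls = 10,
                     exposure = c(base, supplement_user_prob = 1),
                     n_population = 2000, seed = 8)
  ph1 <- simulate_exposure_covariates(cfg1)
  expect_true(all(ph1$supp_folate_mcg == 400))
  cfg2 <- sim_config(n_cases = 10, n_controls = 10,
                     exposure = c(base, supplement_user_prob = 0.3),
                     n_population = 50000, seed = 9)
  ph2 <- simulate_exposure_covariates(cfg2)
  expect_lt(abs(median(ph2$diet_folate_mcg) - 300) / 300, 0.05)
  expect_true(all(ph2$diet_folate_mcg >= 0 & ph2$energy_kcal > 0))
})

test_that("the disease model hits its intercept-implied prevalence", {
  cfg <- sim_config(n_cases = 100, n_controls = 100,
                    effects = list(intercept = qlogis(0.1)),
                    n_population = 30000, seed = 12)
  b <- simulate_cohort(cfg)
  pf <- b$truth$population_case_fraction
  se <- sqrt(0.1 * 0.9 / 30000)
  expect_lt(abs(pf - 0.1), 3 * se)
  expect_identical(sum(b$cohort$status), 100L)
  # requesting more cases than the population can supply is an error
  cfg_bad <- sim_config(n_cases = 20000, n_controls = 100,
                        effects = list(intercept = qlogis(0.05)),
                        n_population = 30000, seed = 12)
  expect_error(simulate_cohort(cfg_bad), "intercept")
})

test_that("a logistic refit of the generating model recovers gamma", {
  # estimator-consistency oracle: refit with the generation-time
  # quantities (population quartiles, population-standardized GReX)
  gamma <- 0.3
  hits <- 0
  reps <- 40
  for (r in seq_len(reps)) {
    cfg <- null_scan_config(1, seed = 400 + r, n_cases = 1500,
                            n_controls = 1500, gamma_fixed = gamma,
                            beta_grex = 0.1)
    b <- simulate_cohort(cfg)
    dfe <- compute_dfe(b$cohort$diet_folate_mcg, b$cohort$supp_folate_mcg)
    q <- findInterval(dfe, b$truth$population_quartile_cutpoints)
    ws <- b$weightsets[[1]]
    raw <- drop(b$genotypes$dosage[, ws$variants$variant_id] %*%
                  ws$variants$weight)
    grex <- (raw - b$truth$grex_center[1]) / b$truth$grex_scale[1]
    fit <- suppressWarnings(glm(
      b$cohort$status ~ b$cohort$age + (b$cohort$sex == "male") +
        b$cohort$study + q + grex + I(grex * q),
      family = binomial()))
    est <- coef(summary(fit))["I(grex * q)", ]
    hits <- hits + (abs(est["Estimate"] - gamma) < 1.96 * est["Std. Error"])
  }
  expect_gte(hits / reps, 0.85)
})

test_that("truth stores a generating value for everything estimated", {
  cfg <- null_scan_config(3, seed = 21, n_cases = 100, n_controls = 100)
  b <- simulate_cohort(cfg)
  tr <- b$truth
  expect_length(tr$realized_r2, 3)
  expect_true(all(tr$realized_r2 >= 0 & tr$realized_r2 <= 1))
  expect_length(tr$effects$gamma_fixed, 3)
  expect_length(tr$b_random, 3)
  expect_length(tr$population_quartile_cutpoints, 3)
  expect_true(is.finite(tr$prevalence))
})
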