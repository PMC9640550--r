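# The mixed-effects interaction score test: null-model contracts,
# brute-force oracles, calibration, asymptotic equivalences, and the
# adaptive combination.

test_that("null model solves the likelihood equations", {
  # intercept-only closed form
  y <- rep(c(1, 0), c(30, 70))
  f <- fit_null_model(y, matrix(1, 100))
  expect_equal(unname(f$coef), qlogis(0.3), tolerance = 1e-8)
  # score at the optimum vanishes
  set.seed(6)
  X <- cbind(1, rnorm(300), rbinom(300, 1, 0.5))
  yb <- rbinom(300, 1, plogis(X %*% c(-0.4, 0.5, 0.3)))
  fit <- fit_null_model(yb, X)
  expect_lt(max(abs(crossprod(X, yb - fit$mu))), 1e-6)
  expect_true(all(fit$mu > 0 & fit$mu < 1))
  # matches the reference ML fit
  ref <- glm.fit(X, yb, family = binomial(),
                 control = glm.control(epsilon = 1e-12))
  expect_equal(unname(fit$coef), unname(ref$coefficients),
               tolerance = 1e-8)
})

test_that("null model rejects degenerate inputs", {
  expect_error(fit_null_model(rep(0, 50), matrix(1, 50)), "single class")
  # perfect separation
  x <- c(rep(-2, 25), rep(2, 25))
  y <- as.integer(x > 0)
  expect_error(fit_null_model(y, cbind(1, x)), "separation")
  # aliased columns are dropped with a message
  set.seed(8)
  X <- cbind(1, rnorm(100))
  X <- cbind(X, dup = X[, 2])
  yb <- rbinom(100, 1, 0.5)
  expect_message(f <- fit_null_model(yb, X), "aliased")
  expect_length(f$coef, 2)
})

test_that("score statistics match the explicit projection-matrix oracle", {
  ti <- tiny_instance()
  X1 <- cbind(1, e = ti$e, grex = ti$grex)
  nm <- fit_null_model(ti$y, X1)
  sf <- score_fixed(nm, ti$grex, ti$e)
  # brute force with P formed densely
  W <- diag(nm$mu * (1 - nm$mu))
  P <- W - W %*% X1 %*% solve(t(X1) %*% W %*% X1) %*% t(X1) %*% W
  cc <- ti$grex * ti$e
  expect_equal(sf$U, sum(cc * (ti$y - nm$mu)), tolerance = 1e-10)
  expect_equal(sf$V, drop(t(cc) %*% P %*% cc), tolerance = 1e-10)
  expect_equal(sf$p, pchisq(sf$U^2 / sf$V, 1, lower.tail = FALSE))

  X2 <- cbind(X1, gxe = ti$grex * ti$e)
  nm2 <- fit_null_model(ti$y, X2)
  sr <- score_random(nm2, ti$G, ti$e)
  W2 <- diag(nm2$mu * (1 - nm2$mu))
  P2 <- W2 - W2 %*% X2 %*% solve(t(X2) %*% W2 %*% X2) %*% t(X2) %*% W2
  Cm <- sweep(ti$G * ti$e, 2, colMeans(ti$G * ti$e))
  expect_equal(sr$Q, sum(crossprod(Cm, ti$y - nm2$mu)^2), tolerance = 1e-10)
  lam_oracle <- sort(eigen(t(Cm) %*% P2 %*% Cm, symmetric = TRUE)$values,
                     decreasing = TRUE)
  expect_equal(sr$lambda, lam_oracle[seq_along(sr$lambda)],
               tolerance = 1e-10)
})

test_that("degenerate interaction columns are flagged, not mis-tested", {
  ti <- tiny_instance()
  X1 <- cbind(1, e = ti$e, grex = ti$grex)
  nm <- fit_null_model(ti$y, X1)
  sf <- score_fixed(nm, rep(0, 8), ti$e)
  expect_true(sf$degenerate)
  expect_true(is.na(sf$p))
  X2 <- cbind(X1, gxe = ti$grex * ti$e)
  nm2 <- fit_null_model(ti$y, X2)
  sr0 <- score_random(nm2, matrix(0, 8, 3), ti$e)
  expect_true(sr0$degenerate)
  expect_identical(sr0$Q, 0)
  expect_true(is.na(sr0$p))
})

test_that("p_fixed is invariant under affine rescaling of E and GReX", {
  cfg <- null_scan_config(1, seed = 55, n_cases = 500, n_controls = 500)
  sc <- run_scan(cfg)
  tab <- sc$table
  y <- tab$status
  X0 <- covariate_matrix(tab)
  e <- tab$folate_q - 1
  grex <- sc$grex$grex[, 1]
  p0 <- score_fixed(fit_null_model(y, cbind(X0, e = e, grex = grex)),
                    grex, e)$p
  e2 <- 10 * e - 7; g2 <- -0.5 * grex + 3
  p1 <- score_fixed(fit_null_model(y, cbind(X0, e = e2, grex = g2)),
                    g2, e2)$p
  expect_equal(p0, p1, tolerance = 1e-8)
})

test_that("score and Wald fixed-interaction tests agree asymptotically", {
  ratios <- replicate(30, NA_real_)
  for (r in seq_len(30)) {
    cfg <- null_scan_config(1, seed = 700 + r, n_cases = 2500,
                            n_controls = 2500, gamma_fixed = 0.15,
                            beta_grex = 0.1)
    sc <- run_scan(cfg)
    tab <- sc$table; grex <- sc$grex$grex[, 1]; e <- tab$folate_q - 1
    wald <- suppressWarnings(glm(
      tab$status ~ covariate_matrix(tab) - 1 + e + grex + I(grex * e),
      family = binomial()))
    pw <- coef(summary(wald))["I(grex * e)", "Pr(>|z|)"]
    ratios[r] <- log10(sc$scan$p_fixed[1]) / log10(pw)
  }
  expect_gte(median(ratios), 0.85)
  expect_lte(median(ratios), 1.15)
})

test_that("random-component p agrees with a resampling oracle", {
  # parametric bootstrap under the fitted null: regenerate y from the
  # fitted probabilities, refit, recompute Q with the same interaction
  # columns -- a reference that involves no eigenvalues and no
  # weighted-chi-square tail
  set.seed(1)
  stats_dav <- stats_boot <- numeric(30)
  for (r in seq_len(30)) {
    cfg <- null_scan_config(1, seed = 900 + r, n_cases = 250,
                            n_controls = 250)
    sc <- run_scan(cfg)
    tab <- sc$table
    grex <- sc$grex$grex[, 1]; e <- tab$folate_q - 1
    G <- sc$grex$aligned[[1]]$dosage
    X2 <- cbind(covariate_matrix(tab), e = e, grex = grex,
                gxe = grex * e)
    nm2 <- fit_null_model(tab$status, X2)
    sr <- score_random(nm2, G, e)
    Cm <- sweep(G * e, 2, colMeans(G * e))
    qs <- replicate(500, {
      ys <- rbinom(length(nm2$mu), 1, nm2$mu)
      nms <- fit_null_model(ys, X2, start = nm2$coef,
                            check_rank = FALSE)
      sum(crossprod(Cm, nms$resid)^2)
    })
    stats_dav[r] <- sr$p
    stats_boot[r] <- (1 + sum(qs >= sr$Q)) / (1 + length(qs))
  }
  expect_gt(cor(rank(stats_dav), rank(stats_boot)), 0.95)
})

test_that("adaptive combination anchors and fallbacks are exact", {
  expect_identical(combine_adaptive(0.0371, 0.9, weight_grid = 1)$p,
                   0.0371)
  expect_identical(combine_adaptive(0.9, 0.0371, weight_grid = 0)$p,
                   0.0371)
  fisher <- combine_adaptive(0.05, 0.05, weight_grid = 0.5)$p
  expect_equal(fisher, pchisq(-2 * log(0.05 * 0.05), 4,
                              lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(abs(fisher - 0.0175), 1e-4)
  # undefined components fall back to the defined one
  expect_identical(combine_adaptive(0.2, NA)$p, 0.2)
  expect_identical(combine_adaptive(NA, 0.3)$p, 0.3)
  expect_true(is.na(combine_adaptive(NA, NA)$p))
  # batch path equals the scalar path
  set.seed(10)
  pf <- runif(20); pr <- runif(20)
  expect_equal(combine_adaptive_batch(pf, pr),
               mapply(function(a, b) combine_adaptive(a, b)$p, pf, pr))
})

test_that("adaptive p-values are uniform for independent null components", {
  set.seed(1)
  n <- 1e5
  pa <- combine_adaptive_batch(runif(n), runif(n))
  expect_uniform_ks(pa)
  expect_lt(abs(mean(pa < 0.05) - 0.05), 0.005)
})

test_that("a single-variant gene falls back to the fixed component", {
  cfg <- sim_config(n_cases = 400, n_controls = 400,
                    blocks = list(list(n_variants = 1,
                                       maf_range = c(0.3, 0.3), rho = 0)),
                    genes = data.frame(gene_id = "G1", block = 1,
                                       n_nonzero_weights = 1,
                                       target_r2 = 0.2),
                    seed = 61)
  sc <- run_scan(cfg)
  row <- sc$scan[1, ]
  expect_match(row$flags, "single_variant")
  expect_identical(row$p_adaptive, row$p_fixed)
  expect_true(is.na(row$p_random))
})

test_that("the genome scan is deterministic and flags, never drops", {
  cfg <- null_scan_config(5, seed = 77, n_cases = 400, n_controls = 400)
  sc1 <- run_scan(cfg)
  sc2 <- run_scan(cfg)
  expect_identical(sc1$scan, sc2$scan)
  expect_identical(nrow(sc1$scan), 5L)
  expect_true(all(sc1$scan$p_adaptive > 0 & sc1$scan$p_adaptive <= 1))
})

test_that("component p-values are empirically independent under the null", {
  # pooled across the calibration cohorts of the acceptance suite's
  # conditions, at reduced scale
  ps <- NULL
  for (s in 1:2) {
    sc <- run_scan(null_scan_config(150, seed = 80 + s, n_cases = 1000,
                                    n_controls = 1000))
    ps <- rbind(ps, sc$scan[, c("p_fixed", "p_random")])
  }
  r <- cor(qnorm(ps$p_fixed), qnorm(ps$p_random))
  expect_lt(abs(r), 0.1)
})
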