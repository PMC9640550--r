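# The statistical engine: per-gene mixed-effects score test for
# gene-environment interaction. The fixed component is a 1-df score
# test of the standardized-GReX-by-exposure product; the random
# component is a variance-component score test of residual
# variant-by-exposure interactions, with a weighted-chi-square null;
# the two are merged by a data-adaptive weighted combination.

#' Covariate design matrix for the pooled logistic models
#'
#' Intercept, age (years), male indicator, study fixed-effect
#' indicators (first study is the reference), the centered energy
#' quartile score (0-3), and any `PC*` columns present.
#'
#' @param table An analysis-ready table from [build_analysis_table()].
#' @return Numeric design matrix with one row per subject.
#' @export
covariate_matrix <- function(table) {
  X <- cbind(`(Intercept)` = 1, age = table$age,
             sex_male = as.numeric(table$sex == "male"))
  studies <- sort(unique(table$study))
  if (length(studies) > 1) {
    for (s in studies[-1])
      X <- cbind(X, as.numeric(table$study == s))
    colnames(X)[(ncol(X) - length(studies) + 2):ncol(X)] <-
      paste0("study_", studies[-1])
  }
  X <- cbind(X, energy_q = table$energy_q - 1)
  pcs <- grep("^PC[0-9]+$", names(table), value = TRUE)
  for (p in pcs) X <- cbind(X, stats::setNames(list(table[[p]]), p)[[1]])
  if (length(pcs)) colnames(X)[(ncol(X) - length(pcs) + 1):ncol(X)] <- pcs
  X
}

#' Fit the covariate-adjusted logistic null model
#'
#' Maximum-likelihood logistic regression by iteratively reweighted
#' least squares (at most 50 iterations, relative log-likelihood change
#' below 1e-10). Aliased columns are dropped with a message; perfect
#' separation (fitted probabilities within 1e-10 of 0 or 1) and
#' one-class outcomes raise errors. The returned object carries what
#' the score tests need: fitted probabilities, residuals, IRLS weights
#' and a Cholesky factor of the weighted information, so quadratic
#' forms in the efficient-score projection
#' `P = W - WX (X'WX)^-1 X'W` never form P explicitly.
#'
#' @param y Binary outcome vector (0/1).
#' @param X Design matrix (including intercept).
#' @param start Optional starting coefficients (aligned to `X`).
#' @param check_rank Detect and drop aliased columns first (skippable
#'   when the caller has already verified the design, as the genome
#'   scan does once per cohort).
#' @return A `null_model` list: `coef`, `mu`, `resid` (`y - mu`), `w`,
#'   `X`, `chol_info`, `converged`, `dropped` (aliased column names).
#' @export
fit_null_model <- function(y, X, start = NULL, check_rank = TRUE) {
  if (length(unique(y)) < 2L)
    stop_config("outcome has a single class; null model not estimable")
  X <- as.matrix(X)
  dropped <- character(0)
  if (check_rank) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      keep <- sort(qrX$pivot[seq_len(qrX$rank)])
      dropped <- colnames(X)[-keep]
      message(sprintf("fit_null_model: dropping aliased columns: %s",
                      paste(dropped, collapse = ", ")))
      X <- X[, keep, drop = FALSE]
      if (!is.null(start)) start <- start[keep]
    }
  }
  fit <- .irls_fit(y, X, start = start)
  mu <- fit$mu
  if (any(mu < 1e-10 | mu > 1 - 1e-10))
    stop_config("fitted probabilities reached 0/1: perfect separation")
  if (!fit$converged)
    stop_config("IRLS did not converge within 50 iterations")
  structure(list(coef = fit$coef, mu = mu, resid = y - mu,
                 w = fit$w, X = X, chol_info = fit$chol_info,
                 converged = fit$converged, dropped = dropped),
            class = "null_model")
}

# Maximum-likelihood logistic regression by iteratively reweighted
# least squares (Fisher scoring): at most `maxit` iterations, declared
# converged when the relative deviance change falls below `epsilon`.
.irls_fit <- function(y, X, start = NULL, epsilon = 1e-10, maxit = 50L) {
  p <- ncol(X)
  beta <- if (!is.null(start) && all(is.finite(start))) start
  else c(stats::qlogis(mean(y)), rep(0, p - 1L))
  dev_old <- Inf
  converged <- FALSE
  ch <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-15), 1 - 1e-15)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    ch <- tryCatch(chol(crossprod(X * sw)), error = function(e) NULL)
    if (is.null(ch))
      stop_config("IRLS failed: weighted information is singular")
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(X, w * z)))
    dev <- -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
    if (is.finite(dev_old) &&
        abs(dev - dev_old) / (abs(dev) + 0.1) < epsilon) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  list(coef = stats::setNames(drop(beta), colnames(X)), mu = mu, w = w,
       chol_info = chol(crossprod(X * sqrt(w))), converged = converged,
       dev = -2 * sum(y * log(pmax(mu, 1e-300)) +
                        (1 - y) * log(pmax(1 - mu, 1e-300))))
}

# C' P C with P = W - WX (X'WX)^-1 X'W, computed from the stored
# Cholesky factor without forming P.
quad_form_proj <- function(null, C) {
  C <- as.matrix(C)
  sw <- sqrt(null$w)
  A <- crossprod(C * sw)
  XtWC <- crossprod(null$X * null$w, C)
  Z <- forwardsolve(t(null$chol_info), XtWC)
  A - crossprod(Z)
}

#' Fixed-component score test of the GReX-by-exposure interaction
#'
#' With the null model containing the exposure trend and the GReX main
#' effect, the interaction column is `c_i = grex_i * e_i`; the score is
#' `U = c'(y - mu)`, its null variance `V = c'Pc`, and
#' `p = P(chisq_1 > U^2/V)`.
#'
#' @param null A `null_model` including main effects of `e` and `grex`.
#' @param grex Standardized predicted expression.
#' @param e Centered exposure quartile score (0-3).
#' @return List: `U`, `V`, `p` (NA with `degenerate = TRUE` when
#'   `V <= 1e-12`).
#' @export
score_fixed <- function(null, grex, e) {
  cc <- grex * e
  U <- sum(cc * null$resid)
  V <- drop(quad_form_proj(null, cc))
  if (!is.finite(V) || V <= 1e-12)
    return(list(U = U, V = V, p = NA_real_, degenerate = TRUE))
  list(U = U, V = V,
       p = clip_p(stats::pchisq(U^2 / V, df = 1, lower.tail = FALSE)),
       degenerate = FALSE)
}

#' Random-component (variance-component) score test
#'
#' Tests for residual variant-level interaction effects not captured by
#' the fixed GReX-by-exposure term: the null model must therefore also
#' contain that fixed interaction. With centered interaction columns
#' `C_j = G_j * e`, the statistic is `Q = (y-mu)' C C' (y-mu)` with null
#' distribution `sum_k lambda_k chisq_1`, `lambda_k` the eigenvalues of
#' `C'PC`; the tail is computed by [davies_pvalue()] with a Liu-type
#' fallback.
#'
#' @param null2 A `null_model` additionally containing the GReX-by-
#'   exposure fixed interaction.
#' @param G Aligned dosage matrix of the gene's variants.
#' @param e Centered exposure quartile score.
#' @return List: `Q`, `lambda`, `p`, `degenerate`, `fallback`.
#' @export
score_random <- function(null2, G, e) {
  C <- as.matrix(G) * e
  C <- sweep(C, 2, colMeans(C))
  Q <- sum(crossprod(C, null2$resid)^2)
  A <- quad_form_proj(null2, C)
  lambda <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(1e-10, 1e-12 * max(lambda, 0))]
  if (!length(lambda))
    return(list(Q = Q, lambda = numeric(0), p = NA_real_,
                degenerate = TRUE, fallback = FALSE))
  pv <- quadform_pvalue(Q, lambda)
  list(Q = Q, lambda = lambda, p = pv$p, degenerate = FALSE,
       fallback = pv$fallback)
}

#' Data-adaptive combination of the fixed and random p-values
#'
#' For each weight `lambda` on a grid, the weighted statistic
#' `T(lambda) = -2[lambda log p_fixed + (1-lambda) log p_random]` has
#' null distribution `lambda chisq_2 + (1-lambda) chisq_2` (independent
#' components), whose tail is evaluated in closed form (a sum of two
#' scaled exponentials); the endpoints reduce exactly to the individual
#' components and `lambda = 0.5` is Fisher's method. The per-weight
#' p-values are merged by the Cauchy combination into a single
#' combining statistic, and — because the grid values are strongly
#' dependent — that statistic is referred to its exact null
#' distribution under independent uniform components, tabulated once
#' per grid by numerical quadrature. A single-element grid returns the
#' per-weight p-value itself (already exactly uniform), so `grid = 1`
#' reproduces `p_fixed` and `grid = 0.5` is exactly Fisher's method.
#'
#' @param p_fixed,p_random Component p-values in `(0, 1]`; `NA` for an
#'   undefined component falls back to the other one.
#' @param weight_grid Grid of fixed-component weights in `[0, 1]`.
#' @return List: `p` (the adaptive p-value), `per_weight` (named vector
#'   of per-lambda p-values), `raw` (the uncalibrated Cauchy
#'   combination).
#' @export
combine_adaptive <- function(p_fixed, p_random,
                             weight_grid = c(0, 0.25, 0.5, 0.75, 1)) {
  if (is.na(p_fixed) && is.na(p_random))
    return(list(p = NA_real_, per_weight = NULL, raw = NA_real_))
  if (is.na(p_random))
    return(list(p = p_fixed, per_weight = c(`1` = p_fixed),
                raw = p_fixed))
  if (is.na(p_fixed))
    return(list(p = p_random, per_weight = c(`0` = p_random),
                raw = p_random))
  stopifnot(all(weight_grid >= 0 & weight_grid <= 1))
  ac <- .acat_raw(p_fixed, p_random, weight_grid)
  p <- if (length(weight_grid) == 1L) ac$raw
  else clip_p(.combine_null_cdf(weight_grid)(ac$raw))
  list(p = p, per_weight = ac$per, raw = ac$raw)
}

# Exact tail of a*Exp(1) + b*Exp(1), i.e. (a/2) chisq_2 + (b/2) chisq_2:
# the null of the weighted two-component combination statistic.
.two_exp_tail <- function(q, a, b) {
  if (q <= 0) return(1)
  if (abs(a - b) < 1e-12 * max(a, b)) {      # Erlang(2): Fisher case
    return(clip_p(exp(-q / a) * (1 + q / a)))
  }
  clip_p((a * exp(-q / a) - b * exp(-q / b)) / (a - b))
}

# The raw Cauchy-combined value over a weight grid, as a function of the
# two component p-values. Used both to form the combined statistic and
# to tabulate its exact null distribution.
.acat_raw <- function(p_fixed, p_random, weight_grid) {
  per <- vapply(weight_grid, function(l) {
    if (l == 1) return(p_fixed)
    if (l == 0) return(p_random)
    Tl <- -2 * (l * log(p_fixed) + (1 - l) * log(p_random))
    .two_exp_tail(Tl, 2 * l, 2 * (1 - l))
  }, numeric(1))
  list(per = stats::setNames(per, weight_grid),
       raw = if (length(per) == 1L) unname(per) else cauchy_combine(per))
}

.combine_cache <- new.env(parent = emptyenv())

# Raw Cauchy-combined value for vectors of component p-values.
.acat_raw_vec <- function(pf, pr, weight_grid) {
  n <- length(pf)
  per <- vapply(weight_grid, function(l) {
    if (l == 1) return(pf)
    if (l == 0) return(pr)
    Tl <- -2 * (l * log(pf) + (1 - l) * log(pr))
    a <- 2 * l; b <- 2 * (1 - l)
    p <- if (abs(a - b) < 1e-12) exp(-Tl / a) * (1 + Tl / a)
    else (a * exp(-Tl / a) - b * exp(-Tl / b)) / (a - b)
    pmin(pmax(p, P_FLOOR), 1)
  }, numeric(n))
  per <- matrix(per, ncol = length(weight_grid))
  if (length(weight_grid) == 1L) return(drop(per))
  tmat <- matrix(0, n, ncol(per))
  small <- per < 1e-15; big <- per > 1 - 1e-15
  mid <- !small & !big
  tmat[mid] <- tanpi(0.5 - per[mid])
  tmat[small] <- 1 / (per[small] * pi)
  tmat[big] <- -1 / (pmax(1 - per[big], 1e-300) * pi)
  stat <- rowMeans(tmat)
  raw <- ifelse(stat > 1e15, 1 / (stat * pi), 0.5 - atan(stat) / pi)
  pmin(pmax(raw, P_FLOOR), 1)
}

# Exact null CDF of the raw Cauchy-combined value under independent
# uniform components, tabulated once per weight grid with a
# deterministic two-dimensional Fibonacci lattice rule (quasi-Monte
# Carlo over the unit square; about 1.3 million nodes, discrepancy
# ~1e-5). Below t = 1e-4 the lattice resolution runs out and the CDF is
# continued linearly through the origin, matching the tabulated value
# at 1e-4 (the Cauchy combination is tail-exact up to a slowly varying
# factor, so the continuation preserves ordering and magnitude).
.combine_null_cdf <- function(weight_grid) {
  key <- paste(format(weight_grid, digits = 10), collapse = "|")
  if (!is.null(.combine_cache[[key]])) return(.combine_cache[[key]])
  N <- 1346269L; A <- 832040L            # consecutive Fibonacci numbers
  i <- seq_len(N) - 1L
  u <- (i + 0.5) / N
  v <- ((i * (A / N)) %% 1 + 0.5 / N) %% 1
  v[v == 0] <- 0.5 / N
  sorted <- sort(.acat_raw_vec(u, v, weight_grid))
  t0 <- 1e-4
  c0 <- findInterval(t0, sorted) / N / t0  # slope of the continuation
  out <- function(t) {
    ifelse(t <= t0, pmin(c0, 2) * t,
           pmin(findInterval(t, sorted) / N, 1))
  }
  .combine_cache[[key]] <- out
  out
}

#' Vectorized adaptive combination
#'
#' Applies [combine_adaptive()] to vectors of component p-values in
#' closed/vectorized form; used for large calibration and power
#' studies.
#'
#' @param p_fixed,p_random Vectors of component p-values; `NA` entries
#'   fall back to the other component.
#' @param weight_grid As in [combine_adaptive()].
#' @return Vector of adaptive p-values.
#' @export
combine_adaptive_batch <- function(p_fixed, p_random,
                                   weight_grid = c(0, 0.25, 0.5, 0.75, 1)) {
  stopifnot(length(p_fixed) == length(p_random))
  n <- length(p_fixed)
  out <- numeric(n)
  both <- !is.na(p_fixed) & !is.na(p_random)
  out[is.na(p_fixed) & is.na(p_random)] <- NA_real_
  out[is.na(p_random) & !is.na(p_fixed)] <-
    p_fixed[is.na(p_random) & !is.na(p_fixed)]
  out[is.na(p_fixed) & !is.na(p_random)] <-
    p_random[is.na(p_fixed) & !is.na(p_random)]
  if (!any(both)) return(out)
  raw <- .acat_raw_vec(p_fixed[both], p_random[both], weight_grid)
  out[both] <- if (length(weight_grid) == 1L) raw
  else clip_p(.combine_null_cdf(weight_grid)(raw))
  out
}

#' Mixed-effects interaction score test for one gene
#'
#' Fits the gene's two null models (covariates + exposure trend + GReX;
#' then additionally the fixed interaction), computes the fixed and
#' random score components and their adaptive combination.
#'
#' @param y Binary outcome.
#' @param X0 Covariate matrix from [covariate_matrix()].
#' @param e Centered exposure quartile score (0-3).
#' @param grex Standardized predicted expression for the gene.
#' @param G Aligned dosage matrix of the gene's variants.
#' @param weight_grid Passed to [combine_adaptive()].
#' @param start0 Optional starting coefficients for the first null fit.
#' @return One-row data frame in the `gene_test_result` schema (without
#'   `gene_id`).
#' @export
gxe_gene_test <- function(y, X0, e, grex, G,
                          weight_grid = c(0, 0.25, 0.5, 0.75, 1),
                          start0 = NULL) {
  flags <- character(0)
  res <- list(n_snps_used = NCOL(G), U_fixed = NA_real_, V_fixed = NA_real_,
              p_fixed = NA_real_, Q_random = NA_real_, p_random = NA_real_,
              p_adaptive = NA_real_)
  if (all(is.na(grex))) {
    return(.gene_row(res, c(flags, "degenerate")))
  }
  X1 <- cbind(X0, e = e, grex = grex)
  null1 <- tryCatch(
    fit_null_model(y, X1, start = if (!is.null(start0))
      c(start0, 0, 0) else NULL, check_rank = FALSE),
    error = function(err) NULL)
  if (is.null(null1)) return(.gene_row(res, c(flags, "null_fit_failed")))
  sf <- score_fixed(null1, grex, e)
  res$U_fixed <- sf$U; res$V_fixed <- sf$V; res$p_fixed <- sf$p
  if (sf$degenerate) flags <- c(flags, "degenerate")

  X2 <- cbind(X1, gxe = grex * e)
  null2 <- tryCatch(
    fit_null_model(y, X2, start = c(null1$coef, 0), check_rank = FALSE),
    error = function(err) NULL)
  if (!is.null(null2) && !is.null(G)) {
    sr <- score_random(null2, G, e)
    res$Q_random <- sr$Q
    res$p_random <- sr$p
    if (sr$degenerate && NCOL(G) == 1L) flags <- c(flags, "single_variant")
    else if (sr$degenerate) flags <- c(flags, "random_degenerate")
    if (sr$fallback) flags <- c(flags, "davies_fallback")
  } else if (is.null(null2)) {
    flags <- c(flags, "null2_fit_failed")
  }
  comb <- combine_adaptive(res$p_fixed, res$p_random, weight_grid)
  res$p_adaptive <- comb$p
  .gene_row(res, unique(flags))
}

.gene_row <- function(res, flags) {
  data.frame(n_snps_used = res$n_snps_used, U_fixed = res$U_fixed,
             V_fixed = res$V_fixed, p_fixed = res$p_fixed,
             Q_random = res$Q_random, p_random = res$p_random,
             p_adaptive = res$p_adaptive,
             flags = paste(flags, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Genome scan: the mixed-effects interaction test over all genes
#'
#' Runs [gxe_gene_test()] for every column of the GReX matrix, reusing
#' the covariate-only fit as warm start. Genes failing preconditions
#' carry flags rather than being dropped.
#'
#' @param table Analysis-ready table with `status`, covariates,
#'   `folate_q`, `energy_q`.
#' @param grex GReX matrix (subjects x genes, standardized) as from
#'   [compute_grex_matrix()].
#' @param aligned Per-gene aligned dosage list (same names as `grex`
#'   columns), as from [compute_grex_matrix()].
#' @param weight_grid Passed to [combine_adaptive()].
#' @param r2 Optional named vector of prediction R2 to report.
#' @return Data frame, one row per gene: `gene_id`, `n_snps_used`,
#'   `r2`, `U_fixed`, `V_fixed`, `p_fixed`, `Q_random`, `p_random`,
#'   `p_adaptive`, `flags`.
#' @export
scan_genome <- function(table, grex, aligned,
                        weight_grid = c(0, 0.25, 0.5, 0.75, 1),
                        r2 = NULL) {
  stopifnot(nrow(table) == nrow(grex))
  y <- table$status
  X0 <- covariate_matrix(table)
  e <- table$folate_q - 1
  base <- fit_null_model(y, cbind(X0, e = e))
  start0 <- base$coef[seq_len(ncol(X0))]
  rows <- vector("list", ncol(grex))
  for (g in seq_len(ncol(grex))) {
    gid <- colnames(grex)[g]
    G <- if (!is.null(aligned[[gid]])) aligned[[gid]]$dosage else NULL
    row <- gxe_gene_test(y, X0, e, grex[, g], G,
                         weight_grid = weight_grid, start0 = start0)
    row <- cbind(gene_id = gid, row, stringsAsFactors = FALSE)
    rows[[g]] <- row
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$r2 <- if (!is.null(r2)) unname(r2[out$gene_id]) else NA_real_
  out[, c("gene_id", "n_snps_used", "r2", "U_fixed", "V_fixed", "p_fixed",
          "Q_random", "p_random", "p_adaptive", "flags")]
}
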