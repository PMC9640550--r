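# Follow-up generalized linear models: quantile-stratified ORs per SD
# of predicted expression, the LD-pruned variant-level driver scan,
# single-variant interaction, and the exposure trend OR. All use Wald
# inference (the scan reserves score tests for the genome pass).

# Logistic fit returning coefficients and their covariance.
.logit_fit <- function(y, X, start = NULL) {
  X <- as.matrix(X)
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    message(sprintf("logistic fit: dropping aliased columns: %s",
                    paste(dropped, collapse = ", ")))
    X <- X[, keep, drop = FALSE]
    if (!is.null(start)) start <- start[keep]
  }
  fit <- .irls_fit(y, X, start = start)
  vcov <- chol2inv(fit$chol_info)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coef = fit$coef, vcov = vcov, converged = fit$converged,
       dropped = dropped)
}

#' Quantile-stratified odds ratios per SD of predicted expression
#'
#' One logistic model with folate quartile indicators, standardized
#' GReX, and GReX-by-quartile interaction terms: the OR per SD change
#' in predicted expression within quartile q is
#' `exp(beta_grex + beta_int_q)` (quartile 1 is the reference), with
#' delta-method Wald CIs; the interaction p-values test each quartile's
#' expression effect against the lowest quartile.
#'
#' @param table Analysis-ready table.
#' @param grex Standardized predicted expression for the gene.
#' @param gene_id Gene label carried into the output.
#' @return Data frame of class `stratified_or_result`: `gene_id`,
#'   `quartile`, `or`, `ci_low`, `ci_high`, `p_int` (NA for quartile 1),
#'   attribute `converged`.
#' @export
stratified_expression_or <- function(table, grex, gene_id = "gene") {
  X0 <- covariate_matrix(table)
  qf <- factor(table$folate_q, levels = 1:4)
  Qi <- stats::model.matrix(~ qf)[, -1, drop = FALSE]
  colnames(Qi) <- paste0("q", 2:4)
  Xint <- Qi * grex
  colnames(Xint) <- paste0("grex_q", 2:4)
  X <- cbind(X0, Qi, grex = grex, Xint)
  fit <- .logit_fit(table$status, X)
  b <- fit$coef; V <- fit$vcov
  out <- vector("list", 4L)
  for (q in 1:4) {
    if (q == 1) {
      est <- b["grex"]; se <- sqrt(V["grex", "grex"]); p <- NA_real_
    } else {
      iq <- paste0("grex_q", q)
      if (!iq %in% names(b)) {  # aliased (e.g. empty quartile)
        out[[q]] <- data.frame(gene_id = gene_id, quartile = q,
                               or = NA_real_, ci_low = NA_real_,
                               ci_high = NA_real_, p_int = NA_real_)
        next
      }
      est <- b["grex"] + b[iq]
      se <- sqrt(V["grex", "grex"] + V[iq, iq] + 2 * V["grex", iq])
      z <- b[iq] / sqrt(V[iq, iq])
      p <- 2 * stats::pnorm(-abs(z))
    }
    out[[q]] <- data.frame(gene_id = gene_id, quartile = q,
                           or = exp(est),
                           ci_low = exp(est - 1.96 * se),
                           ci_high = exp(est + 1.96 * se),
                           p_int = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "converged") <- fit$converged
  class(res) <- c("stratified_or_result", class(res))
  res
}

#' Greedy LD pruning of a variant set
#'
#' Forward pass in genomic position order: a variant is kept iff its
#' squared Pearson correlation with every already-kept variant stays
#' below `r2_max`. The first variant at a position-ordered tie wins,
#' making the survivor set deterministic.
#'
#' @param G Dosage matrix (subjects x variants, named columns).
#' @param positions Genomic positions used for ordering; defaults to
#'   the order of the columns.
#' @param r2_max Squared-correlation threshold (default 0.9).
#' @return Character vector of retained variant ids.
#' @export
prune_variants <- function(G, positions = NULL, r2_max = 0.9) {
  G <- as.matrix(G)
  if (!ncol(G)) stop_config("prune_variants needs at least one variant")
  ord <- if (is.null(positions)) seq_len(ncol(G)) else order(positions)
  sds <- apply(G, 2, stats::sd)
  kept <- integer(0)
  for (j in ord) {
    if (sds[j] < 1e-12) next  # monomorphic: uninformative, drop
    ok <- TRUE
    for (k in kept) {
      if (stats::cor(G[, j], G[, k])^2 >= r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, j)
  }
  colnames(G)[sort(kept)]
}

#' Variant-level interaction driver scan within a gene
#'
#' For each retained variant j, fits one logistic model with the
#' covariates, the exposure trend, main effects of all retained
#' variants, and the single interaction `G_j x E`; reports the ratio of
#' odds ratios `exp(coef)` per quartile increase, its SE and Wald p.
#'
#' @param table Analysis-ready table.
#' @param G Dosage matrix of the gene's variants (prune first with
#'   [prune_variants()]).
#' @param e Centered exposure quartile score; defaults to
#'   `table$folate_q - 1`.
#' @return Data frame: `variant_id`, `ratio_or`, `se`, `ci_low`,
#'   `ci_high`, `p_int`, `converged`.
#' @export
variant_driver_scan <- function(table, G, e = table$folate_q - 1) {
  G <- as.matrix(G)
  X0 <- cbind(covariate_matrix(table), e = e, G)
  rows <- vector("list", ncol(G))
  for (j in seq_len(ncol(G))) {
    X <- cbind(X0, int = G[, j] * e)
    fit <- .logit_fit(table$status, X)
    est <- fit$coef["int"]; se <- sqrt(fit$vcov["int", "int"])
    rows[[j]] <- data.frame(
      variant_id = colnames(G)[j], ratio_or = exp(est), se = se,
      ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
      p_int = 2 * stats::pnorm(-abs(est / se)),
      converged = fit$converged, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Single-variant interaction with the exposure
#'
#' Logistic model with covariates, exposure trend, the variant dosage
#' (per additional effect allele), and its interaction with the
#' quartile score; the exponentiated interaction coefficient is the
#' ratio of odds ratios per quartile increase.
#'
#' @param table Analysis-ready table.
#' @param g Variant dosage vector.
#' @param e Centered exposure quartile score.
#' @param variant_id Label for the output.
#' @return One-row data frame as in [variant_driver_scan()].
#' @export
single_variant_interaction <- function(table, g, e = table$folate_q - 1,
                                       variant_id = "variant") {
  if (stats::sd(e) < 1e-12)
    stop_config("exposure is constant: interaction inestimable")
  if (stats::sd(g) < 1e-12)
    stop_config("variant dosage is constant: interaction inestimable")
  X <- cbind(covariate_matrix(table), e = e, g = g, int = g * e)
  fit <- .logit_fit(table$status, X)
  est <- fit$coef["int"]; se <- sqrt(fit$vcov["int", "int"])
  data.frame(variant_id = variant_id, ratio_or = exp(est), se = se,
             ci_low = exp(est - 1.96 * se),
             ci_high = exp(est + 1.96 * se),
             p_int = 2 * stats::pnorm(-abs(est / se)),
             converged = fit$converged, stringsAsFactors = FALSE)
}

#' Odds ratio of disease per quartile increase in folate intake
#'
#' Logistic model with the standard covariates plus the linear folate
#' quartile score; optionally adds extra covariate columns (e.g.
#' smoking, alcohol) for sensitivity analyses.
#'
#' @param table Analysis-ready table.
#' @param extra Optional matrix/data frame of additional covariates.
#' @return One-row data frame: `or`, `ci_low`, `ci_high`, `p`.
#' @export
exposure_trend_or <- function(table, extra = NULL) {
  X <- covariate_matrix(table)
  if (!is.null(extra)) X <- cbind(X, as.matrix(extra))
  X <- cbind(X, folate_trend = table$folate_q - 1)
  fit <- .logit_fit(table$status, X)
  est <- fit$coef["folate_trend"]
  se <- sqrt(fit$vcov["folate_trend", "folate_trend"])
  data.frame(or = exp(est), ci_low = exp(est - 1.96 * se),
             ci_high = exp(est + 1.96 * se),
             p = 2 * stats::pnorm(-abs(est / se)),
             stringsAsFactors = FALSE)
}
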