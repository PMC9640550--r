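# Multiple-testing control, Q-Q diagnostics, and the descriptive
# case-control characteristics table.

#' Bonferroni genome-scan threshold
#'
#' @param alpha Family-wise error level in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 4839)  # 1.03e-05
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must lie in (0, 1)")
  if (m < 1) stop_config("m must be >= 1")
  alpha / m
}

#' Benjamini-Hochberg discovery flags
#'
#' Step-up FDR control at level `q` via [stats::p.adjust()]; the flag
#' set is monotone in p (no flagged p exceeds an unflagged one) and the
#' boundary is inclusive.
#'
#' @param pvalues Vector of p-values in (0, 1]; `NA`s are never flagged.
#' @param q FDR level (default 0.2).
#' @return Logical vector of discovery flags.
#' @export
bh_fdr <- function(pvalues, q = 0.2) {
  if (!length(pvalues)) return(logical(0))
  if (q <= 0 || q >= 1) stop_config("q must lie in (0, 1)")
  adj <- stats::p.adjust(pvalues, method = "BH")
  flag <- !is.na(adj) & adj <= q
  flag
}

#' Q-Q plot data and genomic-inflation lambda
#'
#' Sorted observed `-log10 p` against `-log10((i - 0.5)/m)`, plus the
#' genomic-control lambda: the median of the p-values' implied 1-df
#' chi-square quantiles over the null median `qchisq(0.5, 1)`.
#'
#' @param pvalues At least 10 p-values in (0, 1].
#' @return Data frame `expected`, `observed` (both `-log10` scale,
#'   ascending) with attribute `lambda`.
#' @export
qq_data <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (length(p) < 10) stop_config("need at least 10 p-values")
  m <- length(p)
  obs <- sort(-log10(clip_p(p)))
  expd <- -log10(((m:1) - 0.5) / m)
  lambda <- stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
  out <- data.frame(expected = expd, observed = obs)
  attr(out, "lambda") <- lambda
  out
}

#' Two-sample t-test from summary statistics
#'
#' Welch (default) or pooled-variance Student t-test computed from
#' group means, SDs and sizes, for descriptive tables built from
#' published summaries rather than microdata.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @param pooled Use the pooled-variance Student test.
#' @return List: `statistic`, `df`, `p.value`.
#' @export
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = FALSE) {
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(statistic = t, df = df,
       p.value = 2 * stats::pt(-abs(t), df = df))
}

#' Case-control characteristics table
#'
#' Per-group n (%) with Pearson chi-square p-values for categorical
#' variables and mean (SD) with two-sample t-test p-values (Welch by
#' default) for continuous ones.
#'
#' @param table Analysis-ready table with `status`.
#' @param categorical,continuous Column names to summarize.
#' @param pooled Use pooled-variance t-tests.
#' @return Data frame: `variable`, `level`, `cases`, `controls`,
#'   `cases_pct`, `controls_pct`, `p` (repeated within variable).
#' @export
cohort_summary <- function(table,
                           categorical = c("sex", "folate_q"),
                           continuous = c("age", "energy_kcal"),
                           pooled = FALSE) {
  stopifnot("status" %in% names(table))
  case <- table$status == 1
  rows <- list()
  for (v in intersect(categorical, names(table))) {
    x <- factor(table[[v]])
    empty <- levels(x)[table(x) == 0]
    if (length(empty)) {
      warning(sprintf("%s: collapsing empty levels: %s", v,
                      paste(empty, collapse = ", ")), call. = FALSE)
      x <- droplevels(x)
    }
    tab <- table(x, factor(case, levels = c(TRUE, FALSE)))
    p <- if (nrow(tab) > 1 && all(colSums(tab) > 0)) {
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    } else NA_real_
    for (l in rownames(tab)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = l,
        cases = tab[l, 1], controls = tab[l, 2],
        cases_pct = 100 * tab[l, 1] / sum(tab[, 1]),
        controls_pct = 100 * tab[l, 2] / sum(tab[, 2]),
        p = p, stringsAsFactors = FALSE)
    }
  }
  for (v in intersect(continuous, names(table))) {
    x1 <- table[[v]][case]; x0 <- table[[v]][!case]
    tt <- summary_ttest(mean(x1), stats::sd(x1), length(x1),
                        mean(x0), stats::sd(x0), length(x0),
                        pooled = pooled)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = "mean (SD)",
      cases = mean(x1), controls = mean(x0),
      cases_pct = stats::sd(x1), controls_pct = stats::sd(x0),
      p = tt$p.value, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
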