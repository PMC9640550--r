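# Genetically predicted expression (GReX): allele alignment of weight
# sets against study genotypes, the linear prediction, and the
# prediction-R2 inclusion filter.

#' Align a weight set's variants to a genotype matrix
#'
#' Variants are matched on `chrom:pos`. An exact ref/effect-allele match
#' uses the dosage as-is; swapped alleles flip the dosage to `2 - d`
#' (logged); any other mismatch, or absence from the genotypes, drops
#' the variant (logged).
#'
#' @param genotypes A `genotype_matrix`.
#' @param weightset A `gene_weight_set`.
#' @return List: `dosage` (subjects x matched variants, flips applied),
#'   `weights` (aligned weight vector), `n_matched`, `n_flipped`,
#'   `n_dropped`, `log` (per-variant action data frame), `untestable`
#'   (`TRUE` when no variant matched).
#' @export
align_variants <- function(genotypes, weightset) {
  vg <- genotypes$variants
  gkey <- paste(vg$chrom, vg$pos, sep = ":")
  wv <- weightset$variants
  wkey <- sub("_.*$", "", wv$variant_id)
  idx <- match(wkey, gkey)
  action <- rep("dropped", nrow(wv))
  flip <- rep(FALSE, nrow(wv))
  hit <- !is.na(idx)
  same <- hit & wv$ref_allele == vg$ref[idx] & wv$effect_allele == vg$alt[idx]
  swap <- hit & wv$ref_allele == vg$alt[idx] & wv$effect_allele == vg$ref[idx]
  action[same] <- "used"
  action[swap] <- "flipped"
  flip[swap] <- TRUE
  use <- same | swap
  log <- data.frame(variant_id = wv$variant_id, action = action,
                    stringsAsFactors = FALSE)
  if (!any(use)) {
    return(list(dosage = NULL, weights = numeric(0), n_matched = 0L,
                n_flipped = 0L, n_dropped = nrow(wv), log = log,
                untestable = TRUE))
  }
  d <- genotypes$dosage[, idx[use], drop = FALSE]
  fl <- flip[use]
  if (any(fl)) d[, fl] <- 2 - d[, fl, drop = FALSE]
  colnames(d) <- wv$variant_id[use]
  # mean-impute missing dosages within a matched variant
  n_imputed <- 0L
  if (anyNA(d)) {
    for (j in seq_len(ncol(d))) {
      na <- is.na(d[, j])
      if (any(na)) {
        d[na, j] <- mean(d[, j], na.rm = TRUE)
        n_imputed <- n_imputed + sum(na)
      }
    }
  }
  list(dosage = d, weights = wv$weight[use],
       n_matched = sum(use), n_flipped = sum(fl),
       n_dropped = sum(!use), n_imputed = n_imputed, log = log,
       untestable = FALSE)
}

#' Predicted expression from aligned dosages and weights
#'
#' The raw prediction for subject i is the dot product
#' `sum_k w_k d_ik`; the standardized form subtracts the mean and
#' divides by the SD over the analysis subjects (cases and controls
#' together). A raw SD of zero flags the gene degenerate and the
#' standardized form is withheld.
#'
#' @param dosage Subjects x variants matrix, alignment already applied.
#' @param weights Weight per variant.
#' @param standardize Compute the standardized form (default `TRUE`).
#' @return A `grex_vector`: list with `raw`, `standardized` (or `NULL`),
#'   `degenerate` flag.
#' @export
predict_expression <- function(dosage, weights, standardize = TRUE) {
  stopifnot(ncol(dosage) == length(weights))
  raw <- drop(dosage %*% weights)
  s <- stats::sd(raw)
  degenerate <- !is.finite(s) || s < 1e-12
  std <- if (standardize && !degenerate) (raw - mean(raw)) / s else NULL
  structure(list(raw = raw, standardized = std, degenerate = degenerate),
            class = "grex_vector")
}

#' Prediction-R2 inclusion filter
#'
#' Keeps genes whose weight-set prediction R2 is at least `r2_min`
#' (boundary inclusive); the scan default of 0.01 retains genes whose
#' variants explain at least 1% of expression variation.
#'
#' @param weightsets List of `gene_weight_set`.
#' @param r2_min Inclusion threshold (default 0.01).
#' @return Character vector of retained gene ids, with attributes
#'   `n_kept` and `n_dropped`.
#' @export
filter_genes <- function(weightsets, r2_min = 0.01) {
  r2 <- vapply(weightsets, `[[`, numeric(1), "pred_r2")
  ids <- vapply(weightsets, `[[`, character(1), "gene_id")
  keep <- r2 >= r2_min
  structure(ids[keep], n_kept = sum(keep), n_dropped = sum(!keep))
}

#' Predicted-expression matrix for a set of genes
#'
#' Runs alignment and prediction for every weight set that passes the
#' R2 filter, producing a subjects x genes matrix of standardized GReX
#' plus an alignment report.
#'
#' @param genotypes A `genotype_matrix`.
#' @param weightsets List of `gene_weight_set`.
#' @param r2_min Passed to [filter_genes()].
#' @return List: `grex` (subjects x genes standardized matrix; columns
#'   for degenerate/untestable genes are `NA`), `alignment` (per-gene
#'   data frame: `gene_id`, `n_matched`, `n_flipped`, `n_dropped`,
#'   `degenerate`, `untestable`), `aligned` (per-gene aligned dosage
#'   matrices, reused by the variance-component test).
#' @export
compute_grex_matrix <- function(genotypes, weightsets, r2_min = 0.01) {
  keep_ids <- filter_genes(weightsets, r2_min)
  ws <- weightsets[match(keep_ids, vapply(weightsets, `[[`, character(1),
                                          "gene_id"))]
  n <- nrow(genotypes$dosage)
  grex <- matrix(NA_real_, n, length(ws),
                 dimnames = list(NULL, keep_ids))
  aligned <- vector("list", length(ws))
  names(aligned) <- keep_ids
  rep_rows <- vector("list", length(ws))
  for (g in seq_along(ws)) {
    al <- align_variants(genotypes, ws[[g]])
    degen <- TRUE
    if (!al$untestable) {
      gx <- predict_expression(al$dosage, al$weights)
      degen <- gx$degenerate
      if (!degen) grex[, g] <- gx$standardized
    }
    aligned[[g]] <- al
    rep_rows[[g]] <- data.frame(
      gene_id = keep_ids[g], n_matched = al$n_matched,
      n_flipped = al$n_flipped, n_dropped = al$n_dropped,
      degenerate = degen, untestable = al$untestable,
      stringsAsFactors = FALSE)
  }
  list(grex = grex,
       alignment = do.call(rbind, c(rep_rows, list(make.row.names = FALSE))),
       aligned = aligned)
}
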