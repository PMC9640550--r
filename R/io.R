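# Readers and writers for the workflow's file formats: phenotype TSV,
# dosage TSV (variants x subjects), PredictDB-style weight TSVs,
# VCF v4.2 with GT and DS, truth/manifest JSON.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a phenotype table
#' @param path TSV with columns `subject_id`, `status`, `age`, `sex`,
#'   `study`, `diet_folate_mcg`, `supp_folate_mcg`, `supp_user`,
#'   `energy_kcal`, `PC1..PCk`.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) .read_tsv(path)

#' Write a phenotype table
#' @param cohort Phenotype data frame.
#' @param path Output TSV path.
#' @export
write_phenotypes <- function(cohort, path) .write_tsv(cohort, path)

#' Read a dosage matrix from TSV (variants in rows, subjects in columns)
#'
#' The first columns are `chrom`, `pos`, `ref`, `alt`, `id`; the rest
#' are per-subject dosages.
#' @param path TSV path.
#' @return A `genotype_matrix`.
#' @export
read_dosage_tsv <- function(path) {
  df <- .read_tsv(path)
  meta <- c("chrom", "pos", "ref", "alt", "id")
  if (!all(meta %in% names(df)))
    stop_config("%s: dosage TSV needs columns %s", path,
                paste(meta, collapse = ", "))
  d <- t(as.matrix(df[, setdiff(names(df), meta), drop = FALSE]))
  colnames(d) <- df$id
  variants <- df[, meta]
  variants$chrom <- as.character(variants$chrom)
  structure(list(dosage = d, variants = variants),
            class = "genotype_matrix")
}

#' Write a genotype matrix as a dosage TSV (variants x subjects)
#' @param genotypes A `genotype_matrix`.
#' @param path Output TSV path.
#' @param subject_ids Column names for subjects.
#' @export
write_dosage_tsv <- function(genotypes, path,
                             subject_ids = sprintf("S%07d",
                                                   seq_len(nrow(genotypes$dosage)))) {
  v <- genotypes$variants[, c("chrom", "pos", "ref", "alt", "id")]
  d <- t(genotypes$dosage)
  colnames(d) <- subject_ids
  .write_tsv(cbind(v, as.data.frame(d, check.names = FALSE)), path)
}

#' Write a genotype matrix as plain VCF v4.2 with GT and DS
#' @inheritParams write_dosage_tsv
#' @export
write_vcf <- function(genotypes, path,
                      subject_ids = sprintf("S%07d",
                                            seq_len(nrow(genotypes$dosage)))) {
  v <- genotypes$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", subject_ids), collapse = "\t")), con)
  d <- genotypes$dosage
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    ds <- d[, j]
    gt <- ifelse(abs(ds - round(ds)) < 1e-9 & ds %in% 0:2,
                 gt_codes[round(ds) + 1L], "./.")
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT:DS",
                       paste0(gt, ":", sprintf("%.6g", ds))),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotype dosages from a VCF (DS preferred, GT fallback)
#'
#' Uses vcfR when installed; otherwise falls back to a minimal reader
#' sufficient for the plain single-allelic VCFs this workflow writes.
#' @param path VCF path.
#' @return A `genotype_matrix`.
#' @export
read_vcf_dosages <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    ds <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE))
    if (is.null(ds) || all(is.na(ds))) {
      gt <- vcfR::extract.gt(vcf, element = "GT")
      ds <- matrix(vapply(gt, function(g) {
        if (is.na(g) || g == "./.") return(NA_real_)
        sum(as.integer(strsplit(g, "[/|]")[[1]]))
      }, numeric(1)), nrow = nrow(gt), dimnames = dimnames(gt))
    }
    variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                           ref = fix$REF, alt = fix$ALT, id = fix$ID,
                           stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "##")]
    header <- strsplit(body[1], "\t")[[1]]
    rows <- strsplit(body[-1], "\t")
    fmt_idx <- which(header == "FORMAT")
    variants <- data.frame(
      chrom = vapply(rows, `[[`, "", 1), pos = as.integer(vapply(rows, `[[`, "", 2)),
      ref = vapply(rows, `[[`, "", 4), alt = vapply(rows, `[[`, "", 5),
      id = vapply(rows, `[[`, "", 3), stringsAsFactors = FALSE)
    ds <- t(vapply(rows, function(r) {
      fmt <- strsplit(r[[fmt_idx]], ":")[[1]]
      k <- match("DS", fmt)
      vapply(r[(fmt_idx + 1):length(r)], function(cell) {
        as.numeric(strsplit(cell, ":")[[1]][k])
      }, numeric(1))
    }, numeric(length(header) - fmt_idx)))
    dimnames(ds) <- list(variants$id, header[(fmt_idx + 1):length(header)])
  }
  d <- t(ds)
  colnames(d) <- variants$id
  structure(list(dosage = d, variants = variants),
            class = "genotype_matrix")
}

#' Write weight sets as PredictDB-style TSVs
#'
#' Emits a per-variant weights TSV (`gene_id`, `gene_name`,
#' `variant_id`, `ref_allele`, `effect_allele`, `weight`) and a gene
#' summary TSV (`gene_id`, `pred_r2`, `n_snps`).
#' @param weightsets List of `gene_weight_set`.
#' @param weights_path,summary_path Output paths.
#' @export
write_weightsets <- function(weightsets, weights_path, summary_path) {
  wrows <- lapply(weightsets, function(ws)
    cbind(gene_id = ws$gene_id, gene_name = ws$gene_name, ws$variants,
          stringsAsFactors = FALSE))
  .write_tsv(do.call(rbind, c(wrows, list(make.row.names = FALSE))),
             weights_path)
  srows <- lapply(weightsets, function(ws)
    data.frame(gene_id = ws$gene_id, pred_r2 = ws$pred_r2,
               n_snps = ws$n_snps, stringsAsFactors = FALSE))
  .write_tsv(do.call(rbind, c(srows, list(make.row.names = FALSE))),
             summary_path)
  invisible(c(weights_path, summary_path))
}

#' Read weight sets from PredictDB-style TSVs
#' @param weights_path,summary_path Paths written by
#'   [write_weightsets()].
#' @return Named list of `gene_weight_set`.
#' @export
read_weightsets <- function(weights_path, summary_path) {
  w <- .read_tsv(weights_path)
  s <- .read_tsv(summary_path)
  ws <- lapply(seq_len(nrow(s)), function(i) {
    gi <- w[w$gene_id == s$gene_id[i], ]
    if (anyDuplicated(gi$variant_id))
      stop_config("gene %s: duplicate variant ids in weights", s$gene_id[i])
    structure(list(gene_id = s$gene_id[i],
                   gene_name = gi$gene_name[1],
                   variants = data.frame(
                     variant_id = gi$variant_id,
                     ref_allele = gi$ref_allele,
                     effect_allele = gi$effect_allele,
                     weight = gi$weight, stringsAsFactors = FALSE),
                   pred_r2 = s$pred_r2[i], n_snps = s$n_snps[i]),
              class = "gene_weight_set")
  })
  names(ws) <- s$gene_id
  ws
}

#' Write the generating truth of a simulated bundle as JSON
#' @param truth A `sim_truth`.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a truth JSON
#' @param path Path written by [write_truth()].
#' @return A `sim_truth` list.
#' @export
read_truth <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "sim_truth")
}

#' Generate a complete on-disk fixture bundle
#'
#' Simulates a cohort and writes every downstream input: phenotype TSV,
#' genotype VCF and dosage TSV, weight and gene-summary TSVs, and the
#' truth JSON. Re-running with the same config reproduces identical
#' files.
#'
#' @param config A [sim_config()].
#' @param outdir Writable output directory (created if needed).
#' @return Named character vector of file paths (invisibly).
#' @export
generate_fixture_bundle <- function(config, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok) stop_config("cannot create output directory %s", outdir)
  bundle <- simulate_cohort(config)
  paths <- c(phenotypes = file.path(outdir, "phenotypes.tsv"),
             vcf = file.path(outdir, "genotypes.vcf"),
             dosages = file.path(outdir, "dosages.tsv"),
             weights = file.path(outdir, "weights.tsv"),
             gene_summary = file.path(outdir, "gene_summary.tsv"),
             truth = file.path(outdir, "truth.json"))
  tryCatch({
    write_phenotypes(bundle$cohort, paths["phenotypes"])
    write_vcf(bundle$genotypes, paths["vcf"],
              subject_ids = bundle$cohort$subject_id)
    write_dosage_tsv(bundle$genotypes, paths["dosages"],
                     subject_ids = bundle$cohort$subject_id)
    write_weightsets(bundle$weightsets, paths["weights"],
                     paths["gene_summary"])
    write_truth(bundle$truth, paths["truth"])
  }, error = function(e) {
    stop_config("fixture bundle write failed under %s: %s", outdir,
                conditionMessage(e))
  })
  invisible(paths)
}
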