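# End-to-end orchestration over an on-disk input bundle: harmonize ->
# predicted expression -> genome scan -> multiple-testing control ->
# follow-up models for flagged genes, with a run manifest.

#' Run the full interaction-scan workflow on an input bundle
#'
#' Reads the phenotype, genotype and weight files, harmonizes the
#' exposure, computes predicted expression, runs the mixed-effects
#' interaction scan, applies Bonferroni and Benjamini-Hochberg control,
#' and routes each flagged gene to a follow-up: genes whose signal is
#' driven by the fixed component (`p_fixed <= p_random`) get
#' quantile-stratified expression ORs; genes driven by the random
#' component get the LD-pruned variant driver scan. Every table is
#' written as TSV under `output_dir` together with a JSON manifest of
#' stage counts.
#'
#' @param input_dir Directory holding `phenotypes.tsv`, `dosages.tsv`
#'   (or `genotypes.vcf` with `use_vcf = TRUE`), `weights.tsv`,
#'   `gene_summary.tsv` (as written by [generate_fixture_bundle()]).
#' @param output_dir Writable output directory.
#' @param r2_min Prediction-R2 inclusion threshold.
#' @param r2_prune LD-pruning squared-correlation threshold.
#' @param alpha Family-wise level for the Bonferroni threshold.
#' @param fdr_q Benjamini-Hochberg level for follow-up flagging.
#' @param weight_grid Adaptive-combination weight grid.
#' @param supplement_mode Passed to [build_analysis_table()].
#' @param use_vcf Read genotypes from the VCF instead of the dosage TSV.
#' @return Invisibly, a list with `table`, `scan`, `followups`,
#'   `manifest`.
#' @export
run_pipeline <- function(input_dir, output_dir, r2_min = 0.01,
                         r2_prune = 0.9, alpha = 0.05, fdr_q = 0.2,
                         weight_grid = c(0, 0.25, 0.5, 0.75, 1),
                         supplement_mode = "dose", use_vcf = FALSE) {
  for (th in c(r2_min, r2_prune, alpha, fdr_q))
    if (th <= 0 || th >= 1) stop_config("thresholds must lie in (0, 1)")
  ok <- dir.exists(output_dir) || dir.create(output_dir, recursive = TRUE)
  if (!ok) stop_config("cannot create %s", output_dir)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_config("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  }

  pheno <- stage("read", read_phenotypes(file.path(input_dir,
                                                   "phenotypes.tsv")))
  geno <- stage("read", if (use_vcf) {
    read_vcf_dosages(file.path(input_dir, "genotypes.vcf"))
  } else read_dosage_tsv(file.path(input_dir, "dosages.tsv")))
  ws <- stage("read", read_weightsets(file.path(input_dir, "weights.tsv"),
                                      file.path(input_dir,
                                                "gene_summary.tsv")))

  tab <- stage("harmonize",
               build_analysis_table(pheno, supplement_mode = supplement_mode))
  .write_tsv(tab, file.path(output_dir, "analysis_table.tsv"))

  subj <- rownames(geno$dosage) %||% pheno$subject_id
  idx <- match(tab$subject_id, subj)
  if (anyNA(idx)) stop_config("pipeline stage 'grex' failed: %d subjects lack genotypes",
                              sum(is.na(idx)))
  geno_sub <- structure(list(dosage = geno$dosage[idx, , drop = FALSE],
                             variants = geno$variants),
                        class = "genotype_matrix")
  gx <- stage("grex", compute_grex_matrix(geno_sub, ws, r2_min = r2_min))
  .write_tsv(cbind(subject_id = tab$subject_id,
                   as.data.frame(gx$grex, check.names = FALSE)),
             file.path(output_dir, "grex_matrix.tsv"))
  .write_tsv(gx$alignment, file.path(output_dir, "alignment_report.tsv"))

  r2 <- vapply(ws, `[[`, numeric(1), "pred_r2")
  names(r2) <- vapply(ws, `[[`, character(1), "gene_id")
  scan <- stage("scan", scan_genome(tab, gx$grex, gx$aligned,
                                    weight_grid = weight_grid, r2 = r2))
  bonf <- bonferroni_threshold(alpha, sum(!is.na(scan$p_adaptive)))
  scan$bonferroni_sig <- !is.na(scan$p_adaptive) & scan$p_adaptive < bonf
  scan$fdr_flag <- bh_fdr(scan$p_adaptive, q = fdr_q)
  scan_out <- scan
  for (cl in c("p_fixed", "p_random", "p_adaptive"))
    scan_out[[cl]] <- ifelse(is.na(scan[[cl]]), NA,
                             sprintf("%.6g", scan[[cl]]))
  .write_tsv(scan_out, file.path(output_dir, "scan_results.tsv"))

  qq <- stage("report", qq_data(scan$p_adaptive[!is.na(scan$p_adaptive)]))
  .write_tsv(qq, file.path(output_dir, "qq_data.tsv"))
  .write_tsv(cohort_summary(tab), file.path(output_dir,
                                            "cohort_summary.tsv"))

  followups <- list(stratified = list(), drivers = list())
  flagged <- scan$gene_id[scan$fdr_flag]
  for (gid in flagged) {
    row <- scan[scan$gene_id == gid, ]
    fixed_driven <- !is.na(row$p_fixed) &&
      (is.na(row$p_random) || row$p_fixed <= row$p_random)
    if (fixed_driven) {
      followups$stratified[[gid]] <- stage(
        "followup", stratified_expression_or(tab, gx$grex[, gid], gid))
    } else {
      G <- gx$aligned[[gid]]$dosage
      pos <- geno$variants$pos[match(colnames(G), geno$variants$id)]
      kept <- stage("followup", prune_variants(G, positions = pos,
                                               r2_max = r2_prune))
      followups$drivers[[gid]] <- stage(
        "followup",
        cbind(gene_id = gid,
              variant_driver_scan(tab, G[, kept, drop = FALSE]),
              stringsAsFactors = FALSE))
    }
  }
  if (length(followups$stratified))
    .write_tsv(do.call(rbind, c(followups$stratified,
                                list(make.row.names = FALSE))),
               file.path(output_dir, "followup_stratified_or.tsv"))
  if (length(followups$drivers))
    .write_tsv(do.call(rbind, c(followups$drivers,
                                list(make.row.names = FALSE))),
               file.path(output_dir, "followup_variant_drivers.tsv"))

  trend <- stage("followup", exposure_trend_or(tab))
  .write_tsv(trend, file.path(output_dir, "exposure_trend_or.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("folategxe")),
    input_dir = normalizePath(input_dir),
    parameters = list(r2_min = r2_min, r2_prune = r2_prune, alpha = alpha,
                      fdr_q = fdr_q, weight_grid = weight_grid,
                      supplement_mode = supplement_mode),
    stages = list(
      harmonize = list(n_subjects = nrow(tab),
                       n_dropped = attr(tab, "n_dropped")),
      grex = list(n_genes_tested = ncol(gx$grex),
                  n_genes_input = length(ws),
                  n_untestable = sum(gx$alignment$untestable)),
      scan = list(n_genes = nrow(scan),
                  bonferroni_threshold = bonf,
                  n_bonferroni = sum(scan$bonferroni_sig),
                  n_fdr_flagged = sum(scan$fdr_flag),
                  lambda = attr(qq, "lambda")),
      followup = list(n_stratified = length(followups$stratified),
                      n_driver_scans = length(followups$drivers))))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(table = tab, scan = scan, followups = followups,
                 trend = trend, manifest = manifest))
}
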