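# Shared fixture builders: everything is generated in code at test time.

# A multi-gene null configuration (no interaction effects), one LD block
# per gene.
null_scan_config <- function(n_genes, seed, n_cases = 2000,
                             n_controls = 2000, n_variants = 5,
                             n_weights = 3, gamma_fixed = 0,
                             tau_random = 0, beta_grex = 0) {
  sim_config(
    n_cases = n_cases, n_controls = n_controls, n_studies = 2,
    blocks = rep(list(list(n_variants = n_variants,
                           maf_range = c(0.1, 0.4), rho = 0.5)), n_genes),
    genes = data.frame(gene_id = sprintf("G%03d", seq_len(n_genes)),
                       block = seq_len(n_genes),
                       n_nonzero_weights = n_weights, target_r2 = 0.1),
    effects = list(intercept = stats::qlogis(0.3), beta_age = 0.2,
                   beta_sex = 0.1, beta_e = -0.05,
                   beta_grex = beta_grex, gamma_fixed = gamma_fixed,
                   tau_random = tau_random),
    seed = seed)
}

# Simulate, harmonize and scan in one go.
run_scan <- function(config) {
  b <- simulate_cohort(config)
  tab <- build_analysis_table(b$cohort)
  gx <- compute_grex_matrix(b$genotypes, b$weightsets)
  list(bundle = b, table = tab, grex = gx,
       scan = scan_genome(tab, gx$grex, gx$aligned))
}

# Hand-built genotype matrix for alignment tests.
toy_genotypes <- function(dosage, chrom = "1",
                          pos = seq(1000, by = 1000,
                                    length.out = ncol(dosage)),
                          ref = rep("A", ncol(dosage)),
                          alt = rep("G", ncol(dosage))) {
  id <- sprintf("%s:%d_%s/%s", chrom, pos, ref, alt)
  colnames(dosage) <- id
  structure(list(dosage = dosage,
                 variants = data.frame(chrom = chrom, pos = pos, ref = ref,
                                       alt = alt, id = id,
                                       stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

toy_weightset <- function(variant_id, ref_allele, effect_allele, weight,
                          gene_id = "G1", pred_r2 = 0.2) {
  structure(list(gene_id = gene_id, gene_name = gene_id,
                 variants = data.frame(variant_id = variant_id,
                                       ref_allele = ref_allele,
                                       effect_allele = effect_allele,
                                       weight = weight,
                                       stringsAsFactors = FALSE),
                 pred_r2 = pred_r2, n_snps = length(weight)),
            class = "gene_weight_set")
}

# A stable 8-subject instance for brute-force score-test oracles: the
# logistic fit has interior fitted probabilities.
tiny_instance <- function() {
  list(y = c(0, 1, 1, 1, 1, 0, 0, 0),
       e = c(0, 1, 2, 3, 0, 1, 2, 3),
       grex = c(1.58, 0.64, 0.09, 0.28, 0.68, 0.09, -2.99, 0.28),
       G = cbind(v1 = c(0, 1, 2, 0, 1, 2, 0, 1),
                 v2 = c(2, 1, 0, 1, 0, 1, 2, 2)))
}

expect_uniform_ks <- function(p, alpha = 0.01) {
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, alpha)
}
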