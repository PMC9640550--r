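# Synthetic cohort generator. Genotypes come from thresholding a latent
# multivariate normal with AR(1) within-block correlation, which gives
# Hardy-Weinberg marginals and LD that decays as rho^|i-j| on the latent
# scale, with a closed-form orthant-probability check available.

#' Simulate LD-blocked biallelic genotype dosages
#'
#' Draws one latent AR(1) Gaussian per block and thresholds it into
#' 0/1/2 dosages so that each variant is marginally in Hardy-Weinberg
#' equilibrium at a minor-allele frequency drawn uniformly from the
#' block's `maf_range` (the alternative allele is the minor one).
#'
#' @param config A [sim_config()].
#' @param n Number of subjects; defaults to the population size.
#' @return A `genotype_matrix`: list with `dosage` (n x variants matrix,
#'   columns named `chr:pos_ref/alt`) and `variants` (data frame with
#'   `chrom`, `pos`, `ref`, `alt`, `id`, `maf`, `block`).
#' @export
simulate_genotypes <- function(config, n = config$n_population) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, 1L, {
    dosage_list <- vector("list", length(config$blocks))
    var_list <- vector("list", length(config$blocks))
    bases <- c("A", "C", "G", "T")
    for (b in seq_along(config$blocks)) {
      blk <- config$blocks[[b]]
      m <- blk$n_variants
      maf <- stats::runif(m, blk$maf_range[1], blk$maf_range[2])
      # latent AR(1): z_j = rho z_{j-1} + sqrt(1-rho^2) eps
      z <- matrix(0, n, m)
      z[, 1] <- stats::rnorm(n)
      if (m > 1) {
        s <- sqrt(1 - blk$rho^2)
        for (j in 2:m) z[, j] <- blk$rho * z[, j - 1] + s * stats::rnorm(n)
      }
      c0 <- stats::qnorm((1 - maf)^2)
      c1 <- stats::qnorm((1 - maf)^2 + 2 * maf * (1 - maf))
      d <- (sweep(z, 2, c0, `>`)) + (sweep(z, 2, c1, `>`))
      ref <- sample(bases, m, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
      pos <- 1000000L * b + 5000L * seq_len(m)
      id <- sprintf("%d:%d_%s/%s", b, pos, ref, alt)
      colnames(d) <- id
      dosage_list[[b]] <- d
      var_list[[b]] <- data.frame(chrom = as.character(b), pos = pos,
                                  ref = ref, alt = alt, id = id,
                                  maf = maf, block = b,
                                  stringsAsFactors = FALSE)
    }
    variants <- do.call(rbind, var_list)
    rownames(variants) <- NULL
    structure(list(dosage = do.call(cbind, dosage_list),
                   variants = variants),
              class = "genotype_matrix")
  })
}

#' Simulate sparse expression weight sets with a target prediction R2
#'
#' For each configured gene, picks `n_nonzero_weights` variants inside
#' its LD block, draws normal weights, and simulates a latent expression
#' trait `G w + noise` with the noise variance set so the in-sample R2
#' of the genetic score on the trait lands near `target_r2`. The
#' realized R2 is stored as the weight set's prediction R2, mirroring
#' how PredictDB-style weight files carry their training R2.
#'
#' @param genotypes A `genotype_matrix` covering the population.
#' @param config A [sim_config()].
#' @return List with `weightsets` (list of `gene_weight_set`),
#'   `expression` (subjects x genes matrix of the latent traits) and
#'   `realized_r2` (named vector).
#' @export
simulate_weightsets <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- config$genes
  with_stream(config$seed, 2L, {
    n <- nrow(genotypes$dosage)
    ws <- vector("list", nrow(genes))
    expr <- matrix(NA_real_, n, nrow(genes),
                   dimnames = list(NULL, genes$gene_id))
    r2 <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
    for (g in seq_len(nrow(genes))) {
      in_block <- which(genotypes$variants$block == genes$block[g])
      k <- genes$n_nonzero_weights[g]
      idx <- sort(sample(in_block, k))
      w <- stats::rnorm(k, sd = 0.3)
      w[w == 0] <- 0.1
      G <- genotypes$dosage[, idx, drop = FALSE]
      score <- drop(G %*% w)
      v <- stats::var(score)
      if (v < 1e-12)
        stop_config("gene %s: genetic score has zero variance", genes$gene_id[g])
      t_r2 <- genes$target_r2[g]
      noise_sd <- sqrt(v * (1 - t_r2) / t_r2)
      trait <- score + stats::rnorm(n, sd = noise_sd)
      r2[g] <- stats::cor(score, trait)^2
      vrec <- genotypes$variants[idx, ]
      ws[[g]] <- structure(list(
        gene_id = genes$gene_id[g],
        gene_name = genes$gene_id[g],
        variants = data.frame(variant_id = vrec$id,
                              ref_allele = vrec$ref,
                              effect_allele = vrec$alt,
                              weight = w, stringsAsFactors = FALSE),
        pred_r2 = unname(r2[g]),
        n_snps = k), class = "gene_weight_set")
      expr[, g] <- trait
    }
    names(ws) <- genes$gene_id
    list(weightsets = ws, expression = expr, realized_r2 = r2)
  })
}

#' Simulate exposure and covariate fields
#'
#' Dietary folate and total energy are log-normal; supplemental folic
#' acid is a point mass at `supplement_dose` for a Bernoulli fraction of
#' users; age is a truncated normal; sex is balanced; studies are
#' uniform; principal-component covariates are standard normal.
#'
#' @param config A [sim_config()].
#' @param n Number of subjects; defaults to the population size.
#' @return A phenotype data frame without outcome: `subject_id`, `age`,
#'   `sex`, `study`, `diet_folate_mcg`, `supp_folate_mcg`, `supp_user`,
#'   `energy_kcal`, `PC1..PCk`.
#' @export
simulate_exposure_covariates <- function(config, n = config$n_population) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, 3L, {
    ex <- config$exposure
    age <- pmin(pmax(stats::rnorm(n, config$age$mean, config$age$sd), 18), 90)
    sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "male", "female")
    study <- sprintf("study_%02d", sample.int(config$n_studies, n,
                                              replace = TRUE))
    diet <- stats::rlnorm(n, ex$log_mean, ex$log_sd)
    user <- stats::rbinom(n, 1, ex$supplement_user_prob)
    supp <- user * ex$supplement_dose
    energy <- stats::rlnorm(n, config$energy$log_mean, config$energy$log_sd)
    out <- data.frame(subject_id = sprintf("S%07d", seq_len(n)),
                      age = age, sex = sex, study = study,
                      diet_folate_mcg = diet, supp_folate_mcg = supp,
                      supp_user = ifelse(user == 1, "yes", "no"),
                      energy_kcal = energy, stringsAsFactors = FALSE)
    if (config$n_pcs > 0) {
      pcs <- matrix(stats::rnorm(n * config$n_pcs), n,
                    dimnames = list(NULL, paste0("PC", seq_len(config$n_pcs))))
      out <- cbind(out, as.data.frame(pcs))
    }
    out
  })
}

#' Simulate disease status and subsample a case-control set
#'
#' The population disease probability is the inverse logit of
#' `intercept + beta_age*(age-mean)/10 + beta_sex*male + study effects +
#' beta_e*q + sum_g [beta_grex_g*GReX_g + gamma_fixed_g*GReX_g*q +
#' sum_j b_gj*G_j*q]` with `b_gj ~ N(0, tau_random_g^2)` (plus any
#' deterministic `b_fixed` coefficients) and `q` the
#' population-quartile folate code (0-3). `n_cases` cases and
#' `n_controls` controls are then drawn without replacement.
#'
#' Note the deliberate, realistic mismatch: generation uses population
#' quartiles of dietary folate equivalents while the analysis re-derives
#' control-based sex-by-study quartiles.
#'
#' @param cohort Output of [simulate_exposure_covariates()].
#' @param genotypes Population `genotype_matrix`.
#' @param weightsets Output of [simulate_weightsets()].
#' @param config A [sim_config()].
#' @return List: `cohort` (sampled rows with `status`), `keep` (row
#'   indices into the population), and `truth` (a `sim_truth`).
#' @export
simulate_outcome <- function(cohort, genotypes, weightsets, config) {
  stopifnot(inherits(config, "sim_config"))
  eff <- config$effects
  n <- nrow(cohort)
  dfe <- compute_dfe(cohort$diet_folate_mcg, cohort$supp_folate_mcg)
  cuts <- stats::quantile(dfe, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  q <- (dfe > cuts[1]) + (dfe > cuts[2]) + (dfe > cuts[3])  # 0..3

  eta <- eff$intercept +
    eff$beta_age * (cohort$age - mean(cohort$age)) / 10 +
    eff$beta_sex * (cohort$sex == "male")
  study_idx <- as.integer(factor(cohort$study))
  if (config$n_studies > 1)
    eta <- eta + c(0, eff$beta_study)[study_idx]
  eta <- eta + eff$beta_e * q

  genes <- config$genes
  b_random <- vector("list", nrow(genes))
  names(b_random) <- genes$gene_id
  grex_center <- grex_scale <- stats::setNames(numeric(nrow(genes)),
                                               genes$gene_id)
  grex_pop <- matrix(NA_real_, n, nrow(genes),
                     dimnames = list(NULL, genes$gene_id))
  with_stream(config$seed, 4L, {
    for (g in seq_len(nrow(genes))) {
      wsg <- weightsets$weightsets[[g]]
      G <- genotypes$dosage[, wsg$variants$variant_id, drop = FALSE]
      raw <- drop(G %*% wsg$variants$weight)
      grex_center[g] <- mean(raw)
      grex_scale[g] <- stats::sd(raw)
      grex <- (raw - grex_center[g]) / grex_scale[g]
      grex_pop[, g] <- grex
      eta <- eta + eff$beta_grex[g] * grex + eff$gamma_fixed[g] * grex * q
      b <- if (eff$tau_random[g] > 0) {
        stats::rnorm(ncol(G), sd = eff$tau_random[g])
      } else rep(0, ncol(G))
      if (!is.null(eff$b_fixed[[genes$gene_id[g]]]))
        b <- b + eff$b_fixed[[genes$gene_id[g]]]
      if (any(b != 0)) eta <- eta + drop((G * q) %*% b)
      names(b) <- wsg$variants$variant_id
      b_random[[g]] <- b
    }
    prob <- stats::plogis(eta)
    y <- stats::rbinom(n, 1, prob)
    case_idx <- which(y == 1)
    ctrl_idx <- which(y == 0)
    if (length(case_idx) < config$n_cases)
      stop_config(paste0(
        "only %d cases generated but %d requested; ",
        "increase the intercept (or n_population)"),
        length(case_idx), config$n_cases)
    if (length(ctrl_idx) < config$n_controls)
      stop_config(paste0(
        "only %d controls generated but %d requested; ",
        "decrease the intercept (or increase n_population)"),
        length(ctrl_idx), config$n_controls)
    keep <- c(sample(case_idx, config$n_cases),
              sample(ctrl_idx, config$n_controls))
    sampled <- cohort[keep, , drop = FALSE]
    sampled$status <- y[keep]
    rownames(sampled) <- NULL
    sampled <- sampled[, c("subject_id", "status",
                           setdiff(names(sampled),
                                   c("subject_id", "status")))]
    truth <- structure(list(
      realized_r2 = weightsets$realized_r2,
      effects = eff,
      b_random = b_random,
      grex_center = grex_center,
      grex_scale = grex_scale,
      prevalence = mean(prob),
      population_case_fraction = mean(y),
      population_quartile_cutpoints = cuts,
      n_population = n,
      seed = config$seed), class = "sim_truth")
    list(cohort = sampled, keep = keep, truth = truth,
         grex_population = grex_pop)
  })
}

#' Run the full generator and return a sampled study bundle
#'
#' Convenience wrapper chaining genotype, weight-set, exposure and
#' outcome simulation, subsetting every population-level object to the
#' sampled case-control set.
#'
#' @param config A [sim_config()].
#' @return A `sim_bundle`: list with `cohort` (phenotypes + status),
#'   `genotypes` (sampled `genotype_matrix`), `weightsets`,
#'   `expression` (sampled latent traits) and `truth`.
#' @export
simulate_cohort <- function(config) {
  geno <- simulate_genotypes(config)
  ws <- simulate_weightsets(geno, config)
  pheno <- simulate_exposure_covariates(config)
  out <- simulate_outcome(pheno, geno, ws, config)
  structure(list(
    cohort = out$cohort,
    genotypes = structure(list(
      dosage = geno$dosage[out$keep, , drop = FALSE],
      variants = geno$variants), class = "genotype_matrix"),
    weightsets = ws$weightsets,
    expression = ws$expression[out$keep, , drop = FALSE],
    truth = out$truth), class = "sim_bundle")
}
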