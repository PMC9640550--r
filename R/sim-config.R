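#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the full description of a simulated case-control
#' study: LD-blocked genotypes, sparse expression weight sets with a
#' target prediction R-squared, a right-skewed folate exposure with a
#' supplement-user mixture, study/sex structure, and a logistic disease
#' model carrying main effects plus a fixed predicted-expression-by-
#' exposure interaction and/or dispersed variant-level interactions.
#'
#' @param n_cases,n_controls Number of cases/controls retained after
#'   case-control subsampling of the simulated population.
#' @param n_studies Number of studies; subjects are assigned uniformly.
#' @param blocks List of LD blocks, each `list(n_variants, maf_range =
#'   c(lo, hi), rho)` with `maf_range` in `(0, 0.5]` and AR(1) latent
#'   correlation `rho` in `[0, 1)`.
#' @param genes Data frame (or list of lists) with columns `gene_id`,
#'   `block` (1-based block index), `n_nonzero_weights`, `target_r2`
#'   in `(0, 1)`.
#' @param exposure List: `log_mean`, `log_sd` of dietary folate
#'   (mcg/day, log-normal); `supplement_user_prob` in `[0, 1]`;
#'   `supplement_dose` (mcg/day given use).
#' @param effects List of generating coefficients on the logit scale:
#'   `intercept`, `beta_age` (per 10 years, age centered), `beta_sex`
#'   (male vs female), `beta_study` (length `n_studies - 1`, study 1
#'   reference), `beta_e` (per folate-quartile increase), `beta_grex`
#'   (main effect of standardized predicted expression, recycled over
#'   genes), `gamma_fixed` (fixed interaction, recycled), `tau_random`
#'   (SD of variant-level interaction effects, recycled), and
#'   optionally `b_fixed` — a named list (by gene id) of deterministic
#'   variant-level interaction coefficients, one per weight-set
#'   variant in order, added on top of any `tau_random` draws.
#' @param n_pcs Number of standard-normal principal-component covariates.
#' @param n_population Population size simulated before case-control
#'   subsampling; `NULL` auto-sizes it from the intercept-implied
#'   prevalence with 25% headroom.
#' @param energy List: `log_mean`, `log_sd` of total energy (kcal/day).
#' @param age List: `mean`, `sd` (years, truncated to `[18, 90]`).
#' @param seed Integer seed; fully determines every draw.
#' @return A validated `sim_config` object.
#' @examples
#' cfg <- sim_config(n_cases = 100, n_controls = 100, seed = 1)
#' @export
sim_config <- function(n_cases = 2000, n_controls = 2000, n_studies = 2,
                       blocks = list(list(n_variants = 8,
                                          maf_range = c(0.1, 0.4),
                                          rho = 0.5)),
                       genes = data.frame(gene_id = "G1", block = 1,
                                          n_nonzero_weights = 4,
                                          target_r2 = 0.1),
                       exposure = list(log_mean = log(300), log_sd = 0.5,
                                       supplement_user_prob = 0.3,
                                       supplement_dose = 400),
                       effects = list(intercept = stats::qlogis(0.25),
                                      beta_age = 0.2, beta_sex = 0.1,
                                      beta_study = NULL, beta_e = 0,
                                      beta_grex = 0, gamma_fixed = 0,
                                      tau_random = 0),
                       n_pcs = 3, n_population = NULL,
                       energy = list(log_mean = log(1900), log_sd = 0.35),
                       age = list(mean = 62, sd = 9),
                       seed = 1L) {
  genes <- as.data.frame(genes)
  if (!all(c("gene_id", "block", "n_nonzero_weights", "target_r2") %in%
           names(genes)))
    stop_config("genes must have gene_id, block, n_nonzero_weights, target_r2")
  if (any(c(n_cases, n_controls, n_studies) <= 0))
    stop_config("counts must be positive")
  for (b in blocks) {
    if (b$n_variants <= 0) stop_config("block n_variants must be positive")
    if (b$rho < 0 || b$rho >= 1)
      stop_config("block rho must lie in [0, 1), got %g", b$rho)
    if (any(b$maf_range <= 0) || any(b$maf_range > 0.5))
      stop_config("maf_range must lie in (0, 0.5]")
  }
  if (any(genes$block < 1 | genes$block > length(blocks)))
    stop_config("gene block index out of range")
  if (any(genes$target_r2 <= 0 | genes$target_r2 >= 1))
    stop_config("target_r2 must lie strictly in (0, 1); boundary genes should use e.g. 0.01")
  nblk <- vapply(blocks, function(b) b$n_variants, numeric(1))
  if (any(genes$n_nonzero_weights > nblk[genes$block]))
    stop_config("n_nonzero_weights exceeds the block's variant count")
  p <- exposure$supplement_user_prob
  if (p < 0 || p > 1) stop_config("supplement_user_prob must lie in [0, 1]")

  eff <- utils::modifyList(
    list(intercept = stats::qlogis(0.25), beta_age = 0, beta_sex = 0,
         beta_study = NULL, beta_e = 0, beta_grex = 0, gamma_fixed = 0,
         tau_random = 0, b_fixed = NULL),
    effects)
  if (!is.null(eff$b_fixed)) {
    if (is.null(names(eff$b_fixed)) ||
        !all(names(eff$b_fixed) %in% genes$gene_id))
      stop_config("b_fixed must be a list named by gene id")
    for (g in names(eff$b_fixed)) {
      k <- genes$n_nonzero_weights[genes$gene_id == g]
      if (length(eff$b_fixed[[g]]) != k)
        stop_config("b_fixed[[%s]] must have %d coefficients", g, k)
    }
  }
  if (is.null(eff$beta_study)) eff$beta_study <- rep(0, n_studies - 1)
  if (length(eff$beta_study) != n_studies - 1)
    stop_config("beta_study must have length n_studies - 1")
  ng <- nrow(genes)
  for (f in c("beta_grex", "gamma_fixed", "tau_random"))
    eff[[f]] <- rep_len(eff[[f]], ng)
  if (any(eff$tau_random < 0)) stop_config("tau_random must be >= 0")

  if (is.null(n_population)) {
    prev <- stats::plogis(eff$intercept)
    n_population <- ceiling(1.25 * max(n_cases / prev,
                                       n_controls / (1 - prev)))
  }
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_studies = n_studies, blocks = blocks, genes = genes,
                 exposure = exposure, effects = eff, n_pcs = n_pcs,
                 n_population = as.integer(n_population),
                 energy = energy, age = age, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d+%d subjects from a population of %d, %d studies\n",
    x$n_cases, x$n_controls, x$n_population, x$n_studies))
  cat(sprintf("  %d LD blocks (%d variants), %d genes, seed %d\n",
              length(x$blocks),
              sum(vapply(x$blocks, `[[`, numeric(1), "n_variants")),
              nrow(x$genes), x$seed))
  invisible(x)
}
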