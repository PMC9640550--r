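# Exposure harmonization: dietary folate equivalents and control-based
# sex-by-study quantile coding.

#' Total folate intake as dietary folate equivalents (DFE)
#'
#' Supplemental folic acid is more bioavailable than food folate, so
#' total intake is `dietary + 1.7 * supplemental` mcg DFE/day. Studies
#' that recorded only regular supplement use (yes/no) have the dose
#' imputed as 400 mcg/day for users, the generic supplement dose;
#' unknown use is treated as non-use (conservative toward the null)
#' with a warning.
#'
#' @param diet_folate_mcg Dietary folate, mcg/day (vector, `>= 0`).
#' @param supp_folate_mcg Supplemental folic acid, mcg/day; supply this
#'   or `supp_user`, not both.
#' @param supp_user Character/logical vector of regular-use flags
#'   (`"yes"`/`"no"`/`"unknown"`, or `TRUE`/`FALSE`/`NA`).
#' @param user_dose_mcg Imputed dose for regular users (default 400).
#' @return Total folate, mcg DFE/day.
#' @examples
#' compute_dfe(300, 400)              # 980
#' compute_dfe(200, supp_user = "yes")  # 880
#' @export
compute_dfe <- function(diet_folate_mcg, supp_folate_mcg = NULL,
                        supp_user = NULL, user_dose_mcg = 400) {
  if (any(diet_folate_mcg < 0, na.rm = TRUE))
    stop_config("dietary folate must be non-negative")
  if (is.null(supp_folate_mcg) == is.null(supp_user))
    stop_config("supply exactly one of supp_folate_mcg or supp_user")
  if (!is.null(supp_user)) {
    if (is.character(supp_user) || is.factor(supp_user)) {
      u <- tolower(as.character(supp_user))
      bad <- !u %in% c("yes", "no", "unknown") & !is.na(u)
      if (any(bad)) stop_config("supp_user values must be yes/no/unknown")
      n_unknown <- sum(u == "unknown" | is.na(u))
      supp_user <- u == "yes"
    } else {
      n_unknown <- sum(is.na(supp_user))
    }
    if (n_unknown > 0)
      warning(sprintf(
        "%d subjects with unknown supplement use treated as non-users",
        n_unknown), call. = FALSE)
    supp_user[is.na(supp_user)] <- FALSE
    supp_folate_mcg <- ifelse(supp_user, user_dose_mcg, 0)
  }
  if (any(supp_folate_mcg < 0, na.rm = TRUE))
    stop_config("supplemental folic acid must be non-negative")
  diet_folate_mcg + 1.7 * supp_folate_mcg
}

#' Control-based sex-by-study quartile codes
#'
#' Cutpoints are the 25th/50th/75th empirical percentiles (linear
#' interpolation between order statistics, `quantile` type 7) of the
#' control values within each (sex, study) stratum; every subject in
#' the stratum — case or control — is then coded 1-4 with ties at a
#' cutpoint going to the lower code. A stratum whose control values are
#' all identical codes everyone 1 with a warning.
#'
#' @param values Intake values (e.g. mcg DFE/day).
#' @param sex,study Stratifying factors, one value per subject.
#' @param status 0 = control, 1 = case; cutpoints use controls only.
#' @param min_controls Minimum controls per stratum (default 8).
#' @return List of class `exposure_quantiles`: `code` (integer 1-4 per
#'   subject), `cutpoints` (data frame `sex`, `study`, `c25`, `c50`,
#'   `c75`, `n_controls`).
#' @export
assign_stratified_quartiles <- function(values, sex, study, status,
                                        min_controls = 8L) {
  stopifnot(length(values) == length(sex),
            length(values) == length(study),
            length(values) == length(status))
  if (any(is.na(values))) stop_config("values contain NA; filter first")
  strat <- interaction(sex, study, drop = TRUE, sep = "|")
  code <- integer(length(values))
  cp <- list()
  for (s in levels(strat)) {
    in_s <- strat == s
    ctrl <- values[in_s & status == 0]
    if (length(ctrl) < min_controls)
      stop_config("stratum %s has %d controls (< %d)", s, length(ctrl),
                  min_controls)
    parts <- strsplit(s, "|", fixed = TRUE)[[1]]
    if (max(ctrl) - min(ctrl) == 0) {
      warning(sprintf("stratum %s: all control values identical; coding 1", s),
              call. = FALSE)
      code[in_s] <- 1L
      cuts <- rep(ctrl[1], 3)
    } else {
      cuts <- stats::quantile(ctrl, c(0.25, 0.5, 0.75), type = 7,
                              names = FALSE)
      v <- values[in_s]
      code[in_s] <- 1L + (v > cuts[1]) + (v > cuts[2]) + (v > cuts[3])
    }
    cp[[s]] <- data.frame(sex = parts[1], study = parts[2],
                          c25 = cuts[1], c50 = cuts[2], c75 = cuts[3],
                          n_controls = length(ctrl),
                          stringsAsFactors = FALSE)
  }
  structure(list(code = code, cutpoints = do.call(rbind, c(cp, list(
    make.row.names = FALSE))))
    , class = "exposure_quantiles")
}

#' Build the analysis-ready table
#'
#' Harmonizes total folate to DFE, drops rows with missing folate or
#' energy (complete-case, counts logged as messages), and adds the
#' control-based sex-by-study quartile codes for folate (`folate_q`)
#' and total energy (`energy_q`), both 1-4.
#'
#' @param cohort Phenotype data frame with at least `status`, `age`,
#'   `sex`, `study`, `diet_folate_mcg`, `energy_kcal`, and either
#'   `supp_folate_mcg` or `supp_user` per the study's supplement mode.
#' @param supplement_mode Named character vector mapping study id to
#'   `"dose"` or `"binary"`; unnamed scalar applies to all studies
#'   (default `"dose"`).
#' @param min_controls Passed to [assign_stratified_quartiles()].
#' @return The input rows that survive complete-case filtering, with
#'   added columns `folate_dfe`, `folate_q`, `energy_q`; attributes
#'   `n_dropped`, `folate_cutpoints`, `energy_cutpoints`.
#' @export
build_analysis_table <- function(cohort, supplement_mode = "dose",
                                 min_controls = 8L) {
  req <- c("status", "age", "sex", "study", "diet_folate_mcg", "energy_kcal")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) stop_config("missing columns: %s",
                                paste(miss, collapse = ", "))
  if (length(supplement_mode) == 1L && is.null(names(supplement_mode)))
    supplement_mode <- stats::setNames(
      rep(supplement_mode, length(unique(cohort$study))),
      unique(cohort$study))
  dfe <- rep(NA_real_, nrow(cohort))
  for (st in unique(cohort$study)) {
    rows <- cohort$study == st
    mode <- supplement_mode[[st]] %||% "dose"
    dfe[rows] <- if (mode == "binary") {
      compute_dfe(cohort$diet_folate_mcg[rows],
                  supp_user = cohort$supp_user[rows])
    } else {
      compute_dfe(cohort$diet_folate_mcg[rows],
                  supp_folate_mcg = cohort$supp_folate_mcg[rows])
    }
  }
  keep <- !is.na(dfe) & !is.na(cohort$energy_kcal) & cohort$energy_kcal > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("build_analysis_table: dropped %d rows with missing folate/energy",
                    n_dropped))
  tab <- cohort[keep, , drop = FALSE]
  if (!nrow(tab)) stop_config("no usable rows after complete-case filtering")
  tab$folate_dfe <- dfe[keep]
  fq <- assign_stratified_quartiles(tab$folate_dfe, tab$sex, tab$study,
                                    tab$status, min_controls)
  eq <- assign_stratified_quartiles(tab$energy_kcal, tab$sex, tab$study,
                                    tab$status, min_controls)
  tab$folate_q <- fq$code
  tab$energy_q <- eq$code
  rownames(tab) <- NULL
  attr(tab, "n_dropped") <- n_dropped
  attr(tab, "folate_cutpoints") <- fq$cutpoints
  attr(tab, "energy_cutpoints") <- eq$cutpoints
  tab
}
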