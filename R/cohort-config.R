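#' Build a synthetic-cohort configuration
#'
#' Bundles everything the cohort generator needs: latent group proportions,
#' per-group polynomial trajectory coefficients on centered age for each
#' phenotype, residual scales, bounded scale specifications, distal-outcome
#' generating means, and per-phenotype per-wave missingness targets with a
#' missing-at-random dependence coefficient.
#'
#' Trajectory polynomials are evaluated on `age - center_age`, so intercepts
#' are mid-trajectory levels; this keeps the design matrix well conditioned
#' for ages spanning childhood to mid-adolescence.
#'
#' @param n_subjects Number of subjects to generate.
#' @param ages Strictly increasing assessment ages (years).
#' @param groups Tibble with columns `group` (1..J), `label`, `proportion`
#'   (summing to 1).
#' @param coeffs Tibble with columns `group`, `phenotype`, `b0`, `b1`, `b2`:
#'   polynomial coefficients on centered age.
#' @param sigma Tibble with columns `phenotype`, `sigma` (> 0): residual SD
#'   of the latent (pre-censoring) score.
#' @param scales Scale specification tibble, see [scale_specs()].
#' @param outcomes Tibble with columns `outcome`, `sd`, `observed_fraction`,
#'   or `NULL` for a cohort without distal outcomes.
#' @param outcome_means Tibble with columns `outcome`, `group`, `mean`.
#' @param missingness Tibble with columns `phenotype`, `age`, `rate`: target
#'   marginal missing probability per phenotype-wave (in `[0, 1)`), or `NULL`
#'   for complete panels.
#' @param mar_gamma Coefficient of the subject's previous-wave observed score
#'   in the logistic missingness model (per score unit). Positive values make
#'   higher-scoring subjects more likely to go missing, a missing-at-random
#'   mechanism since it conditions only on observed data.
#' @param center_age Centering constant for the age polynomials (years).
#' @param outcome_lognormal If `TRUE`, distal outcomes are drawn lognormal
#'   (matched mean/SD) instead of normal, for robustness experiments.
#' @param monotone_dropout If `TRUE`, a subject missing at one wave stays
#'   missing at later waves (dropout); default is intermittent missingness.
#'
#' @return A `cohort_config` object (a validated list).
#' @seealso [default_cohort_config()], [simulate_cohort()]
#' @export
cohort_config <- function(n_subjects, ages, groups, coeffs, sigma, scales,
                          outcomes = NULL, outcome_means = NULL,
                          missingness = NULL, mar_gamma = 0.03,
                          center_age = 11, outcome_lognormal = FALSE,
                          monotone_dropout = FALSE) {
  stopifnot(is.numeric(n_subjects), n_subjects >= 1)
  ages <- as.numeric(ages)
  if (any(diff(ages) <= 0)) stop("ages must be strictly increasing", call. = FALSE)
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("group", "label", "proportion") %in% names(groups)))
  if (abs(sum(groups$proportion) - 1) > 1e-12)
    stop("group proportions must sum to 1", call. = FALSE)
  if (any(groups$proportion <= 0 | groups$proportion > 1))
    stop("group proportions must lie in (0, 1]", call. = FALSE)
  coeffs <- tibble::as_tibble(coeffs)
  stopifnot(all(c("group", "phenotype", "b0", "b1", "b2") %in% names(coeffs)))
  if (!all(is.finite(as.matrix(coeffs[, c("b0", "b1", "b2")]))))
    stop("trajectory coefficients must be finite", call. = FALSE)
  sigma <- tibble::as_tibble(sigma)
  if (any(sigma$sigma <= 0)) stop("residual sigma must be positive", call. = FALSE)
  phens <- scales$phenotype
  missing_combo <- setdiff(
    paste(rep(groups$group, each = length(phens)), phens),
    paste(coeffs$group, coeffs$phenotype))
  if (length(missing_combo))
    stop("coeffs must cover every group x phenotype combination", call. = FALSE)
  if (!is.null(outcomes)) {
    outcomes <- tibble::as_tibble(outcomes)
    stopifnot(all(c("outcome", "sd", "observed_fraction") %in% names(outcomes)))
    if (any(outcomes$sd <= 0)) stop("outcome sd must be positive", call. = FALSE)
    if (any(outcomes$observed_fraction <= 0 | outcomes$observed_fraction > 1))
      stop("observed_fraction must lie in (0, 1]", call. = FALSE)
    outcome_means <- tibble::as_tibble(outcome_means)
    stopifnot(all(c("outcome", "group", "mean") %in% names(outcome_means)))
  }
  if (!is.null(missingness)) {
    missingness <- tibble::as_tibble(missingness)
    stopifnot(all(c("phenotype", "age", "rate") %in% names(missingness)))
    if (any(missingness$rate < 0 | missingness$rate >= 1))
      stop("missingness rates must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), ages = ages, groups = groups,
         coeffs = coeffs, sigma = sigma, scales = scales,
         outcomes = outcomes, outcome_means = outcome_means,
         missingness = missingness, mar_gamma = mar_gamma,
         center_age = center_age, outcome_lognormal = outcome_lognormal,
         monotone_dropout = monotone_dropout),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  subjects:", x$n_subjects, " ages:", paste(x$ages, collapse = ", "), "\n")
  cat("  groups:", nrow(x$groups), "(",
      paste(sprintf("%s=%.3f", x$groups$label, x$groups$proportion),
            collapse = ", "), ")\n")
  cat("  phenotypes:", paste(x$scales$phenotype, collapse = ", "), "\n")
  if (!is.null(x$outcomes)) cat("  distal outcomes:", nrow(x$outcomes), "\n")
  cat("  missingness:", if (is.null(x$missingness)) "none" else "MAR targets set", "\n")
  invisible(x)
}

#' Example pooled group-mean table
#'
#' A pooled-results table from a six-group multi-trajectory analysis of a
#' community cohort (phenotypes measured at ages 7-15, twelve outcomes at
#' age 20): per-outcome, per-group pooled means, standard errors adjusted
#' for between-imputation variation, and 95% confidence bounds. Used as a
#' worked example for the confidence-interval arithmetic and the overlap
#' screen, and as the default distal-outcome generating means of
#' [default_cohort_config()].
#'
#' @return Tibble with columns `outcome`, `group`, `mean`, `se`, `ci_lo`,
#'   `ci_hi`.
#' @export
pooled_outcomes_example <- function() {
  path <- system.file("extdata", "pooled_outcomes_example.csv",
                      package = "trajmix", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    outcome = "c", group = "c",
                    mean = "d", se = "d", ci_lo = "d", ci_hi = "d"))
}

# Per-phenotype per-wave observed counts used to calibrate default MAR rates
# (out of 1620 enrolled subjects).
default_wave_counts <- function() {
  ages <- c(7, 8, 9, 10, 11, 12, 13, 15)
  tibble::tibble(
    phenotype = rep(c("adhd", "internalising", "externalising"), each = 8L),
    age = rep(ages, 3L),
    n_observed = c(1312, 1305, 1283, 1252, 1053, 970, 1242, 1276,
                   1302, 1303, 1281, 1240, 1034, 967, 1232, 1265,
                   1263, 1266, 1240, 1213, 1039, 953, 1207, 1221))
}

#' Default six-group cohort configuration
#'
#' The package's reference study design: 1620 subjects, three bounded
#' phenotype scales (ADHD 7-35, internalising 7-35, externalising 17-85)
#' measured at ages 7, 8, 9, 10, 11, 12, 13 and 15, six latent trajectory
#' groups with proportions 32.5%, 27.9%, 10.6%, 13.5%, 12% and 3.4%,
#' missing-at-random wave missingness calibrated to the per-wave observed
#' counts of the reference design, and twelve age-20 distal outcomes with
#' group-specific means taken from [pooled_outcomes_example()].
#'
#' The six trajectory shapes are qualitative: consistently low on all three
#' domains ("unaffected"); mildly elevated then declining ("normative
#' maturing"); elevated internalising only ("internalising"); low start then
#' escalating on all domains ("late onset"); high start then declining on
#' all domains ("remitting"); and persistently high ADHD/internalising with
#' rapidly remitting externalising ("remitting_ext"). The numeric
#' coefficients and residual SDs are synthetic package defaults chosen to
#' realise those shapes at plausible levels - they are not estimates from
#' any fitted model.
#'
#' @param n_subjects Cohort size (default 1620).
#' @return A [cohort_config()] object.
#' @export
default_cohort_config <- function(n_subjects = 1620) {
  ages <- c(7, 8, 9, 10, 11, 12, 13, 15)
  groups <- tibble::tibble(
    group = 1:6,
    label = c("unaffected", "normative_maturing", "internalising",
              "late_onset", "remitting", "remitting_ext"),
    # the published shares sum to 0.999 after rounding; renormalise
    proportion = c(0.325, 0.279, 0.106, 0.135, 0.12, 0.034) / 0.999)
  coeffs <- tibble::tribble(
    ~group, ~phenotype, ~b0, ~b1, ~b2,
    1L, "adhd",          10.0,  0.0,  0.00,
    1L, "internalising", 10.0,  0.0,  0.00,
    1L, "externalising", 19.0,  0.0,  0.00,
    2L, "adhd",          14.0, -0.8,  0.05,
    2L, "internalising", 12.0, -0.5,  0.05,
    2L, "externalising", 24.0, -1.2,  0.10,
    3L, "adhd",          12.0,  0.0,  0.00,
    3L, "internalising", 20.0,  0.0,  0.00,
    3L, "externalising", 21.0,  0.0,  0.00,
    4L, "adhd",          18.0,  1.2,  0.05,
    4L, "internalising", 16.0,  1.0,  0.05,
    4L, "externalising", 30.0,  2.0,  0.10,
    5L, "adhd",          18.0, -1.2,  0.05,
    5L, "internalising", 16.0, -1.0,  0.05,
    5L, "externalising", 30.0, -2.0,  0.10,
    6L, "adhd",          22.0,  0.0,  0.00,
    6L, "internalising", 19.0,  0.0,  0.00,
    6L, "externalising", 26.0, -2.5,  0.15)
  sigma <- tibble::tibble(
    phenotype = c("adhd", "internalising", "externalising"),
    sigma = c(4.5, 4.0, 6.0))
  wave_counts <- default_wave_counts()
  missingness <- dplyr::mutate(wave_counts, rate = 1 - .data$n_observed / 1620)
  missingness <- missingness[, c("phenotype", "age", "rate")]
  ex <- pooled_outcomes_example()
  outcome_names <- unique(ex$outcome)
  outcome_n <- c(social_exclusion = 1176, optimism = 1177, stress = 1180,
                 ipv_phys_perp = 774, ipv_sex_perp = 774, ipv_psych_perp = 773,
                 ipv_monit_perp = 774, ipv_phys_vict = 774, ipv_sex_vict = 775,
                 ipv_psych_vict = 772, ipv_monit_vict = 775, delinquency = 1174)
  outcome_sd <- c(social_exclusion = 3.54, optimism = 2.29, stress = 3.72,
                  ipv_phys_perp = 1.03, ipv_sex_perp = 0.29,
                  ipv_psych_perp = 0.99, ipv_monit_perp = 2.38,
                  ipv_phys_vict = 1.35, ipv_sex_vict = 0.72,
                  ipv_psych_vict = 1.47, ipv_monit_vict = 2.95,
                  delinquency = 2.19)
  outcomes <- tibble::tibble(
    outcome = outcome_names,
    sd = unname(outcome_sd[outcome_names]),
    observed_fraction = unname(outcome_n[outcome_names]) / 1620)
  group_idx <- setNames(groups$group, groups$label)
  outcome_means <- tibble::tibble(
    outcome = ex$outcome,
    group = unname(group_idx[ex$group]),
    mean = ex$mean)
  cohort_config(n_subjects = n_subjects, ages = ages, groups = groups,
                coeffs = coeffs, sigma = sigma, scales = default_scales(),
                outcomes = outcomes, outcome_means = outcome_means,
                missingness = missingness, mar_gamma = 0.03)
}

#' Small three-group cohort configuration
#'
#' A scaled-down design used for calibration studies where the full
#' six-group cohort would be needlessly slow: 400 subjects, the same three
#' phenotype scales and assessment ages, three well-separated trajectory
#' groups (low-stable, escalating, remitting), a uniform 20% MAR missingness
#' target per wave, and four distal outcomes with group-mean separation of
#' about one residual SD.
#'
#' @param n_subjects Cohort size (default 400).
#' @return A [cohort_config()] object.
#' @export
small_cohort_config <- function(n_subjects = 400) {
  ages <- c(7, 8, 9, 10, 11, 12, 13, 15)
  groups <- tibble::tibble(
    group = 1:3,
    label = c("low_stable", "escalating", "remitting"),
    proportion = c(0.5, 0.3, 0.2))
  coeffs <- tibble::tribble(
    ~group, ~phenotype, ~b0, ~b1, ~b2,
    1L, "adhd",          10.0,  0.0, 0.00,
    1L, "internalising", 10.0,  0.0, 0.00,
    1L, "externalising", 19.0,  0.0, 0.00,
    2L, "adhd",          18.0,  1.2, 0.05,
    2L, "internalising", 16.0,  1.0, 0.05,
    2L, "externalising", 30.0,  2.0, 0.10,
    3L, "adhd",          18.0, -1.2, 0.05,
    3L, "internalising", 16.0, -1.0, 0.05,
    3L, "externalising", 30.0, -2.0, 0.10)
  sigma <- tibble::tibble(
    phenotype = c("adhd", "internalising", "externalising"),
    sigma = c(4.5, 4.0, 6.0))
  missingness <- tidyr::expand_grid(
    phenotype = c("adhd", "internalising", "externalising"),
    age = ages)
  missingness$rate <- 0.2
  outcomes <- tibble::tibble(
    outcome = paste0("outcome_", 1:4),
    sd = c(3.0, 2.0, 4.0, 1.5),
    observed_fraction = c(0.75, 0.75, 0.6, 0.6))
  outcome_means <- tidyr::expand_grid(outcome = outcomes$outcome, group = 1:3)
  base <- c(outcome_1 = 10, outcome_2 = 12, outcome_3 = 8, outcome_4 = 5)
  shift <- 1.5 * c(3.0, 2.0, 4.0, 1.5)   # 1.5 residual SDs per group step
  outcome_means$mean <- unname(base[outcome_means$outcome]) +
    shift[match(outcome_means$outcome, outcomes$outcome)] *
    (outcome_means$group - 1)
  cohort_config(n_subjects = n_subjects, ages = ages, groups = groups,
                coeffs = coeffs, sigma = sigma, scales = default_scales(),
                outcomes = outcomes, outcome_means = outcome_means,
                missingness = missingness, mar_gamma = 0.03)
}
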