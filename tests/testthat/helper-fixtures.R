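# Shared fixtures for the test suite; everything is generated in code.

# single-phenotype configuration with well-separated flat/sloped groups,
# used for model-selection and recovery checks
one_phen_config <- function(n, groups = 3L) {
  stopifnot(groups %in% c(1L, 2L, 3L))
  props <- list(1, c(0.5, 0.5), c(0.4, 0.35, 0.25))[[groups]]
  b0 <- c(10, 17, 24)[seq_len(groups)]
  b1 <- c(0, 0.6, -0.6)[seq_len(groups)]
  cohort_config(
    n_subjects = n, ages = c(7, 9, 11, 13, 15),
    groups = tibble::tibble(group = seq_len(groups),
                            label = paste0("g", seq_len(groups)),
                            proportion = props),
    coeffs = tibble::tibble(group = seq_len(groups), phenotype = "adhd",
                            b0 = b0, b1 = b1, b2 = 0),
    sigma = tibble::tibble(phenotype = "adhd", sigma = 2.5),
    scales = scale_specs("adhd", 7, 35))
}

# tiny deterministic long panel for io tests
tiny_panel <- function() {
  tibble::tibble(
    subject_id = c("s1", "s1", "s1"),
    age = c(7, 8, 9),
    phenotype = c("adhd", "adhd", "internalising"),
    score = c(12, NA, 20))
}

# small-cohort variant whose distal outcome means are equal across groups
null_outcome_config <- function(n = 300) {
  cfg <- small_cohort_config(n)
  cfg$outcome_means$mean <- rep(10, nrow(cfg$outcome_means))
  cfg
}

# fast fitting settings used throughout the simulation-based tests; chosen
# so a single fit costs seconds, not minutes
fast <- list(n_starts = 1L, short_iter = 6L, tol = 1e-3, max_iter = 100L)

fit_fast <- function(panel, J, seed = 1L, ...) {
  fit_multitrajectory(panel, J, n_starts = fast$n_starts,
                      short_iter = fast$short_iter, tol = fast$tol,
                      max_iter = fast$max_iter, seed = seed, ...)
}
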