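#' Read a long-format panel file
#'
#' Reads delimited text with columns `subject_id`, `age`, `phenotype`,
#' `score` (empty score cells become missing), validates phenotype labels
#' and scale bounds, and rejects duplicate subject-age-phenotype rows with
#' their row numbers.
#'
#' @param path File path (CSV).
#' @param scales Scale specification tibble, see [scale_specs()].
#' @return A validated panel tibble with a `"scales"` attribute.
#' @export
read_panel <- function(path, scales = default_scales()) {
  panel <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(subject_id = readr::col_character(),
                            age = readr::col_character(),
                            phenotype = readr::col_character(),
                            score = readr::col_double()))
  if (!all(c("subject_id", "age", "phenotype", "score") %in% names(panel)))
    stop("panel file must have columns subject_id, age, phenotype, score",
         call. = FALSE)
  age_num <- suppressWarnings(as.numeric(panel$age))
  if (anyNA(age_num))
    stop("non-numeric age at rows: ",
         paste(head(which(is.na(age_num)), 10L), collapse = ", "),
         call. = FALSE)
  panel$age <- age_num
  unknown <- setdiff(unique(panel$phenotype), scales$phenotype)
  if (length(unknown))
    stop("unknown phenotype labels: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  key <- paste(panel$subject_id, panel$age, panel$phenotype)
  if (anyDuplicated(key))
    stop("duplicate subject-age-phenotype rows at: ",
         paste(head(which(duplicated(key)), 10L), collapse = ", "),
         call. = FALSE)
  joined <- dplyr::left_join(panel, scales, by = "phenotype")
  bad <- which(!is.na(joined$score) &
                 (joined$score < joined$lo | joined$score > joined$hi))
  if (length(bad))
    stop("scores outside scale bounds at rows: ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  attr(panel, "scales") <- scales
  panel
}

#' Write a long-format panel file
#'
#' Missing scores are written as empty cells; [read_panel()] inverts the
#' round trip.
#'
#' @param panel Panel tibble.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- panel[, c("subject_id", "age", "phenotype", "score")]
  out$subject_id <- as.character(out$subject_id)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read / write a long-format distal-outcome file
#'
#' Columns `subject_id`, `outcome`, `value`; empty cells are missing.
#'
#' @param path File path (CSV).
#' @return Tibble with columns `subject_id`, `outcome`, `value`.
#' @export
read_outcomes <- function(path) {
  readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(subject_id = readr::col_character(),
                            outcome = readr::col_character(),
                            value = readr::col_double()))
}

#' @rdname read_outcomes
#' @param outcomes Outcome tibble.
#' @export
write_outcomes <- function(outcomes, path) {
  out <- outcomes[, c("subject_id", "outcome", "value")]
  out$subject_id <- as.character(out$subject_id)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write / read a cohort configuration as YAML
#'
#' @param config A [cohort_config()].
#' @param path YAML file path.
#' @return `write_cohort_config()` returns `path` invisibly;
#'   `read_cohort_config()` returns the reconstructed [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  ser <- lapply(unclass(config), function(x) {
    if (is.data.frame(x)) lapply(as.list(x), unname) else x
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_tbl <- function(x) if (is.null(x)) NULL else tibble::as_tibble(x)
  cohort_config(
    n_subjects = raw$n_subjects,
    ages = unlist(raw$ages),
    groups = as_tbl(raw$groups),
    coeffs = as_tbl(raw$coeffs),
    sigma = as_tbl(raw$sigma),
    scales = as_tbl(raw$scales),
    outcomes = as_tbl(raw$outcomes),
    outcome_means = as_tbl(raw$outcome_means),
    missingness = as_tbl(raw$missingness),
    mar_gamma = raw$mar_gamma,
    center_age = raw$center_age,
    outcome_lognormal = isTRUE(raw$outcome_lognormal),
    monotone_dropout = isTRUE(raw$monotone_dropout))
}
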