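#' Define bounded measurement scales
#'
#' A scale specification records the admissible range of a phenotype's
#' composite (sum) score. Observed scores at the bounds are treated as
#' censored by the tobit emission used throughout the package, which is how
#' floor and ceiling effects in questionnaire sum scores are accommodated.
#'
#' @param phenotype Character vector of phenotype labels.
#' @param lo,hi Numeric vectors of scale minima and maxima (score units).
#'   `-Inf`/`Inf` are allowed and turn the emission into a plain normal.
#'
#' @return A tibble with columns `phenotype`, `lo`, `hi`.
#' @examples
#' scale_specs(c("adhd", "internalising"), lo = 7, hi = 35)
#' @export
scale_specs <- function(phenotype, lo, hi) {
  out <- tibble::tibble(phenotype = as.character(phenotype),
                        lo = as.numeric(lo), hi = as.numeric(hi))
  if (anyDuplicated(out$phenotype))
    stop("duplicate phenotype labels in scale specification", call. = FALSE)
  if (any(is.na(out$lo)) || any(is.na(out$hi)))
    stop("scale bounds must not be NA", call. = FALSE)
  if (any(out$lo >= out$hi))
    stop("scale minimum must be strictly below maximum", call. = FALSE)
  out
}

#' Default phenotype scales
#'
#' Bounds for the three phenotype sum scores modelled by the default cohort
#' configuration: ADHD symptoms and internalising problems on 7-item scales
#' scored 7-35, externalising problems on a 17-item scale scored 17-85.
#'
#' @return A tibble of scale specifications (see [scale_specs()]).
#' @export
default_scales <- function() {
  scale_specs(c("adhd", "internalising", "externalising"),
              lo = c(7, 7, 17), hi = c(35, 35, 85))
}

check_scores_in_bounds <- function(panel, scales) {
  joined <- dplyr::left_join(panel, scales, by = "phenotype")
  if (any(is.na(joined$lo)))
    stop("panel contains phenotypes absent from the scale specification: ",
         paste(unique(panel$phenotype[is.na(joined$lo)]), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(joined$score) &
                 (joined$score < joined$lo | joined$score > joined$hi))
  if (length(bad))
    stop("scores outside scale bounds at rows: ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  invisible(panel)
}
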