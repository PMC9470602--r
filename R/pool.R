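#' Pool estimates across imputations by Rubin's rules
#'
#' Combines one scalar parameter's per-imputation estimates and squared
#' standard errors into a pooled estimate whose total variance adds the
#' mean within-imputation variance and the between-imputation variance
#' inflated by `(1 + 1/M)`.
#'
#' @param estimates Numeric vector of per-imputation point estimates
#'   (length `M >= 2`).
#' @param variances Numeric vector of per-imputation variances (squared
#'   SEs), same length, all non-negative.
#' @return One-row tibble with `qbar` (pooled estimate), `ubar` (mean
#'   within-imputation variance), `b` (between-imputation variance,
#'   denominator `M - 1`), `t_var = ubar + (1 + 1/M) b`, `se = sqrt(t_var)`
#'   and `m`.
#' @examples
#' pool_rubin(c(1, 2, 3), c(0, 0, 0)) # qbar 2, b 1, t_var 4/3
#' @export
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2L) stop("at least two imputations are required", call. = FALSE)
  if (length(variances) != m)
    stop("estimates and variances must have equal length", call. = FALSE)
  if (any(variances < 0)) stop("variances must be non-negative", call. = FALSE)
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- var(estimates)
  t_var <- ubar + (1 + 1 / m) * b
  tibble::tibble(qbar = qbar, ubar = ubar, b = b, t_var = t_var,
                 se = sqrt(t_var), m = m)
}

#' Normal-quantile confidence interval for a pooled estimate
#'
#' `qbar +/- z * se` with the standard-normal quantile (1.959964 at the 95%
#' level). The pooled `se` already carries the between-imputation
#' adjustment, so this is the interval whose non-overlap is screened by
#' [compare_groups_ci()].
#'
#' @param qbar Pooled point estimate(s) (vectorised).
#' @param se Pooled standard error(s), non-negative.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Tibble with columns `ci_lo`, `ci_hi`.
#' @examples
#' ci_from_pooled(12.43, 0.41) # upper bound 13.23 at 2 dp
#' @export
ci_from_pooled <- function(qbar, se, level = 0.95) {
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1)
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  if (any(se < 0)) stop("se must be non-negative", call. = FALSE)
  z <- qnorm((1 + level) / 2)
  tibble::tibble(ci_lo = qbar - z * se, ci_hi = qbar + z * se)
}

#' Pairwise group comparison by confidence-interval overlap
#'
#' Declares a pair of groups significantly different exactly when their
#' confidence intervals do not overlap; intervals sharing an endpoint count
#' as overlapping. This screen is conservative relative to a formal test of
#' the difference, and no multiple-comparison correction is applied.
#'
#' @param intervals Tibble with columns `group`, `ci_lo`, `ci_hi`, one row
#'   per group (a single outcome).
#' @return Tibble of unordered pairs: `group_a`, `group_b`, `significant`.
#'   The decision is symmetric in the pair by construction.
#' @export
compare_groups_ci <- function(intervals) {
  stopifnot(all(c("group", "ci_lo", "ci_hi") %in% names(intervals)))
  if (any(intervals$ci_lo > intervals$ci_hi))
    stop("intervals must have ci_lo <= ci_hi", call. = FALSE)
  if (anyDuplicated(intervals$group))
    stop("one interval per group expected", call. = FALSE)
  n <- nrow(intervals)
  if (n < 2L)
    return(tibble::tibble(group_a = intervals$group[0],
                          group_b = intervals$group[0],
                          significant = logical(0)))
  pairs <- utils::combn(n, 2L)
  a <- pairs[1L, ]; b <- pairs[2L, ]
  sig <- intervals$ci_hi[a] < intervals$ci_lo[b] |
    intervals$ci_hi[b] < intervals$ci_lo[a]
  tibble::tibble(group_a = intervals$group[a],
                 group_b = intervals$group[b],
                 significant = sig)
}

#' Pool per-imputation joint fits into an outcome report table
#'
#' Takes one aligned `joint_fit` per imputation (relabel with
#' [relabel_groups()] first if needed), pools each group x outcome mean by
#' Rubin's rules using the fits' observed-information SEs, and attaches
#' normal-quantile confidence bounds - the tabular analogue of a pooled
#' outcome-by-group report.
#'
#' @param fits List of `joint_fit` objects (length `M >= 2`), label-aligned.
#' @param level Confidence level (default 0.95).
#' @return Tibble of class `pooled_outcomes`: `outcome`, `group`, `mean`,
#'   `se`, `ci_lo`, `ci_hi`, plus the pooling components `ubar` and `b`.
#' @export
pool_outcome_table <- function(fits, level = 0.95) {
  if (length(fits) < 2L)
    stop("at least two imputations are required", call. = FALSE)
  est <- purrr::imap_dfr(fits, function(f, m) {
    out <- f$outcome_means
    if (is.null(out$se))
      stop("joint fits must carry standard errors (fit with se = TRUE)",
           call. = FALSE)
    out$m <- m
    out
  })
  pooled <- est |>
    dplyr::group_by(.data$outcome, .data$group) |>
    dplyr::summarise(
      pool_rubin(.data$mean, .data$se^2),
      .groups = "drop")
  ci <- ci_from_pooled(pooled$qbar, pooled$se, level)
  out <- tibble::tibble(outcome = pooled$outcome, group = pooled$group,
                        mean = pooled$qbar, se = pooled$se,
                        ci_lo = ci$ci_lo, ci_hi = ci$ci_hi,
                        ubar = pooled$ubar, b = pooled$b)
  class(out) <- c("pooled_outcomes", class(out))
  out
}

#' Pool group proportions across imputations
#'
#' Group membership proportions are pooled on the probability scale (the
#' reporting scale), as the simple mean of the per-imputation softmax
#' outputs.
#'
#' @param fits List of label-aligned fitted models.
#' @return Tibble with columns `group`, `proportion`.
#' @export
pool_proportions <- function(fits) {
  P <- vapply(fits, `[[`, numeric(fits[[1L]]$J), "pi")
  tibble::tibble(group = seq_len(fits[[1L]]$J),
                 proportion = rowMeans(as.matrix(P)))
}

#' Significance screen for every outcome in a pooled table
#'
#' Applies [compare_groups_ci()] outcome by outcome.
#'
#' @param pooled A `pooled_outcomes` table (or any tibble with `outcome`,
#'   `group`, `ci_lo`, `ci_hi`).
#' @return Long tibble: `outcome`, `group_a`, `group_b`, `significant`.
#' @export
significance_screen <- function(pooled) {
  pooled |>
    dplyr::group_by(.data$outcome) |>
    dplyr::group_modify(function(df, key) compare_groups_ci(df)) |>
    dplyr::ungroup()
}
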