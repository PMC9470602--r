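#' Simulate a complete synthetic cohort
#'
#' Draws each subject into a latent trajectory group, generates latent
#' phenotype scores as group polynomial trajectories of centered age plus
#' normal noise, clamps them to the scale bounds (so floor/ceiling pile-up
#' mimics censored sum scores), and draws distal outcomes around the
#' group-specific means. The returned panel is complete; wave missingness is
#' applied separately by [apply_mar_missingness()] so the pre-deletion data
#' remain available as ground truth.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; runs with equal seeds are identical.
#'
#' @return A list of class `cohort_sim` with elements `panel` (tibble:
#'   `subject_id`, `age`, `phenotype`, `score`), `outcomes` (tibble:
#'   `subject_id`, `outcome`, `value`, `NA` = missing), `truth` (tibble:
#'   `subject_id`, `group`) and `config`.
#' @examples
#' sim <- simulate_cohort(small_cohort_config(50), seed = 1)
#' dplyr::count(sim$truth, group)
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  n <- config$n_subjects
  labels <- sample.int(nrow(config$groups), n, replace = TRUE,
                       prob = config$groups$proportion)
  cage <- config$ages - config$center_age
  panel <- tidyr::expand_grid(subject_id = seq_len(n),
                              phenotype = config$scales$phenotype,
                              age = config$ages)
  key <- paste(labels[panel$subject_id], panel$phenotype)
  ck <- paste(config$coeffs$group, config$coeffs$phenotype)
  idx <- match(key, ck)
  c_age <- panel$age - config$center_age
  mu <- config$coeffs$b0[idx] + config$coeffs$b1[idx] * c_age +
    config$coeffs$b2[idx] * c_age^2
  sig <- config$sigma$sigma[match(panel$phenotype, config$sigma$phenotype)]
  ystar <- mu + rnorm(nrow(panel), 0, sig)
  sc <- config$scales
  lo <- sc$lo[match(panel$phenotype, sc$phenotype)]
  hi <- sc$hi[match(panel$phenotype, sc$phenotype)]
  panel$score <- pmin(pmax(ystar, lo), hi)
  panel <- panel[, c("subject_id", "age", "phenotype", "score")]

  outcomes <- NULL
  if (!is.null(config$outcomes)) {
    outcomes <- tidyr::expand_grid(subject_id = seq_len(n),
                                   outcome = config$outcomes$outcome)
    om <- config$outcome_means
    oidx <- match(paste(outcomes$outcome, labels[outcomes$subject_id]),
                  paste(om$outcome, om$group))
    m <- om$mean[oidx]
    s <- config$outcomes$sd[match(outcomes$outcome, config$outcomes$outcome)]
    if (isTRUE(config$outcome_lognormal)) {
      # lognormal with matched mean and SD
      cv2 <- (s / m)^2
      sdlog <- sqrt(log1p(cv2))
      meanlog <- log(m) - sdlog^2 / 2
      outcomes$value <- exp(rnorm(nrow(outcomes), meanlog, sdlog))
    } else {
      outcomes$value <- rnorm(nrow(outcomes), m, s)
    }
    keep_frac <- config$outcomes$observed_fraction[
      match(outcomes$outcome, config$outcomes$outcome)]
    outcomes$value[runif(nrow(outcomes)) > keep_frac] <- NA_real_
  }

  structure(
    list(panel = tibble::as_tibble(panel),
         outcomes = if (is.null(outcomes)) NULL else tibble::as_tibble(outcomes),
         truth = tibble::tibble(subject_id = seq_len(n), group = labels),
         config = config),
    class = "cohort_sim")
}

#' Delete panel observations under a missing-at-random mechanism
#'
#' Deletes whole phenotype-wave observations with probability
#' `plogis(alpha_wave + mar_gamma * previous-wave observed score)`. The
#' intercept `alpha_wave` is calibrated by root-finding so that the marginal
#' deletion probability at each phenotype-wave equals the configured target
#' rate. Deletion at a wave depends only on data still observed at earlier
#' waves (never on values already deleted, and never on the value being
#' deleted), so the mechanism is missing at random by construction; for
#' subjects whose previous wave is itself missing, only the intercept is
#' used. With `monotone_dropout = TRUE` in the config, missingness is
#' carried forward as permanent dropout before any additional intermittent
#' deletion needed to reach the target rate.
#'
#' @param panel Complete long panel from [simulate_cohort()].
#' @param config The generating [cohort_config()]; its `missingness` table
#'   supplies the target rates.
#' @param seed Integer seed.
#'
#' @return The panel with deleted scores set to `NA`.
#' @export
apply_mar_missingness <- function(panel, config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (anyNA(panel$score))
    stop("panel must be complete before applying missingness", call. = FALSE)
  if (is.null(config$missingness)) return(panel)
  if (any(config$missingness$rate >= 1))
    stop("missingness rates must be below 1", call. = FALSE)
  set.seed(as.integer(seed))
  gamma <- config$mar_gamma
  miss <- config$missingness
  out <- panel
  subjects <- sort(unique(panel$subject_id))
  for (ph in unique(miss$phenotype)) {
    ph_rows <- which(out$phenotype == ph)
    block <- out[ph_rows, ]
    # wide n x T score matrix for this phenotype
    ages <- sort(unique(miss$age[miss$phenotype == ph]))
    score <- matrix(NA_real_, length(subjects), length(ages),
                    dimnames = list(NULL, ages))
    si <- match(block$subject_id, subjects)
    ti <- match(block$age, ages)
    score[cbind(si, ti)] <- block$score
    observed <- !is.na(score)
    for (t in seq_along(ages)) {
      target <- miss$rate[miss$phenotype == ph & miss$age == ages[t]]
      if (!length(target) || target <= 0) next
      at_risk <- observed[, t]
      if (isTRUE(config$monotone_dropout) && t > 1L) {
        dropped <- !observed[, t - 1L] & at_risk
        observed[dropped, t] <- FALSE
        at_risk <- observed[, t]
        already <- mean(!observed[, t])
        if (already >= target) next
        # residual rate among still-observed subjects to hit the marginal target
        target <- (target - already) / mean(at_risk)
      }
      v <- numeric(length(subjects))
      if (t > 1L) {
        prev <- score[, t - 1L]
        prev[!observed[, t - 1L]] <- NA_real_
        v <- ifelse(is.na(prev), 0, gamma * prev)
      }
      vr <- v[at_risk]
      alpha <- uniroot(function(a) mean(plogis(a + vr)) - target,
                       lower = -50, upper = 50, tol = 1e-10)$root
      p <- plogis(alpha + vr)
      del <- runif(length(vr)) < p
      idx <- which(at_risk)[del]
      observed[idx, t] <- FALSE
    }
    keep <- observed[cbind(si, ti)]
    out$score[ph_rows[!keep]] <- NA_real_
  }
  out
}
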