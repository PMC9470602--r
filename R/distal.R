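# One-step joint estimation of trajectory groups and group-specific distal
# outcome means: the outcome likelihood enters the same mixture as the
# trajectories, so classification uncertainty propagates into the outcome
# means instead of being discarded by a classify-then-analyze shortcut.

# wide n x O outcome matrix aligned to the panel's subject order
outcomes_to_matrix <- function(outcomes, subjects, outcome_names = NULL) {
  stopifnot(all(c("subject_id", "outcome", "value") %in% names(outcomes)))
  unknown <- setdiff(unique(outcomes$subject_id), subjects)
  if (length(unknown))
    stop("outcomes reference subjects absent from the panel: ",
         paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
  outcome_names <- outcome_names %||% unique(outcomes$outcome)
  Z <- matrix(NA_real_, length(subjects), length(outcome_names),
              dimnames = list(NULL, outcome_names))
  Z[cbind(match(outcomes$subject_id, subjects),
          match(outcomes$outcome, outcome_names))] <- outcomes$value
  Z
}

#' Jointly estimate trajectory groups and distal outcome means
#'
#' Extends a fitted multi-trajectory model with group-specific means for
#' distal outcomes, estimated in the same mixture in a single step: the
#' joint likelihood multiplies each subject's trajectory likelihood by
#' normal densities of their observed outcomes around the candidate group's
#' outcome means. Estimation is by EM, warm-started at the trajectory-only
#' fit ("start values provided"), with outcome means initialised at
#' posterior-weighted group means; the joint log-likelihood at the optimum
#' is never below its value at the warm start. Missing outcomes simply drop
#' out of the likelihood (ignorable given group). Standard errors come from
#' the inverse observed information matrix of the full parameter vector, so
#' they reflect classification uncertainty.
#'
#' @param panel Long panel tibble (same data the start model was fitted on).
#' @param outcomes Long tibble with columns `subject_id`, `outcome`,
#'   `value`; `NA` values (or absent rows) are treated as missing.
#' @param start A fitted `multitraj_fit` used as the warm start.
#' @param tol,max_iter,m_maxit EM controls, as in [fit_multitrajectory()].
#' @param se Compute standard errors (default `TRUE`).
#' @param group_var If `TRUE`, outcome residual variances are group-specific
#'   instead of shared across groups.
#' @return Object of class `joint_fit` (also a `multitraj_fit`), adding
#'   `outcome_means` (tibble `outcome`, `group`, `mean`, `se`),
#'   `outcome_sd`, `start_loglik` and `se_ok`.
#' @export
fit_joint <- function(panel, outcomes, start, tol = 1e-6, max_iter = 500L,
                      m_maxit = 10L, se = TRUE, group_var = FALSE) {
  stopifnot(inherits(start, "multitraj_fit"))
  bl <- panel_blocks(panel, start$scales, order = start$order,
                     center_age = start$center_age)
  if (!identical(bl$subjects, start$subjects))
    stop("panel subjects differ from those the start model was fitted on",
         call. = FALSE)
  ocl <- outcomes[!is.na(outcomes$value), , drop = FALSE]
  Z <- outcomes_to_matrix(ocl, bl$subjects)
  O <- ncol(Z)
  J <- start$J

  params <- list(theta = start$theta, beta = start$beta, sigma = start$sigma)
  A_traj <- cond_loglik_matrix(bl, params$beta, params$sigma)
  P0 <- estep(A_traj, params$theta)$P
  up0 <- outcome_mstep(Z, P0, NULL, group_var)
  Mu <- up0$Mu
  osig <- up0$osig

  start_loglik <- {
    A <- A_traj + outcome_cond_loglik(Z, Mu, osig_rows(osig, J))
    estep(A, params$theta)$loglik
  }

  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  P <- P0
  for (it in seq_len(max_iter)) {
    A <- cond_loglik_matrix(bl, params$beta, params$sigma) +
      outcome_cond_loglik(Z, Mu, osig_rows(osig, J))
    e <- estep(A, params$theta)
    trace <- c(trace, e$loglik)
    P <- e$P
    if (is.finite(ll_prev) && e$loglik - ll_prev < -1e-8)
      warning("joint EM log-likelihood decreased by ",
              format(ll_prev - e$loglik), call. = FALSE)
    if (is.finite(ll_prev) && abs(e$loglik - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- e$loglik
    params <- mstep(bl, P, params$beta, params$sigma, m_maxit)
    up <- outcome_mstep(Z, P, list(Mu = Mu, osig = osig), group_var)
    Mu <- up$Mu
    osig <- up$osig
  }
  if (!converged)
    warning("joint EM did not converge in ", max_iter, " iterations",
            call. = FALSE)

  run <- list(params = params, loglik = trace[length(trace)], trace = trace,
              P = P, converged = converged, n_iter = length(trace))
  model <- build_multitraj_fit(bl, run, J, start$order, start$scales,
                               start$center_age, 0L, NA_real_, start$seed)
  model$Mu <- Mu
  model$outcome_names <- colnames(Z)
  model$outcome_sd <- if (group_var) {
    matrix(osig, J, O, dimnames = list(NULL, colnames(Z)))
  } else setNames(osig, colnames(Z))
  model$group_var <- group_var
  model$outcome_means <- tibble::tibble(
    outcome = rep(colnames(Z), each = J),
    group = rep(seq_len(J), O),
    mean = as.vector(Mu))
  model$n_params <- model$n_params + J * O + (if (group_var) J * O else O)
  model$start_loglik <- start_loglik
  class(model) <- c("joint_fit", class(model))

  if (isTRUE(se)) {
    if (group_var) {
      warning("standard errors are only implemented for shared outcome ",
              "variances; skipping", call. = FALSE)
      model$se_ok <- FALSE
    } else {
      d <- param_dims(J, model$K, model$order + 1L, O)
      par <- pack_params(params$theta, params$beta, params$sigma, Mu, osig)
      info <- observed_information(par, function(p)
        joint_loglik_score(p, d, bl, Z)$score)
      ses <- se_from_information(info, par, d)
      model$se_ok <- ses$ok
      if (!ses$ok)
        warning("observed information not positive definite; ",
                "standard errors unavailable", call. = FALSE)
      ose <- if (ses$ok) matrix(ses$se[d$idx$omu], J, O) else
        matrix(NA_real_, J, O)
      model$outcome_se <- tibble::tibble(
        outcome = rep(colnames(Z), each = J),
        group = rep(seq_len(J), O),
        se = as.vector(ose))
      model$outcome_means$se <- as.vector(ose)
    }
  }
  model
}

# shared variance: osig is length-O; group-specific: J x O matrix
osig_rows <- function(osig, J) {
  if (is.matrix(osig)) osig else matrix(osig, J, length(osig), byrow = TRUE)
}

# Closed-form M-step for the outcome block. `prev` carries forward means of
# groups with (numerically) no observed outcome mass.
outcome_mstep <- function(Z, P, prev = NULL, group_var = FALSE) {
  J <- ncol(P); O <- ncol(Z)
  Mu <- matrix(NA_real_, J, O)
  if (group_var) osig <- matrix(NA_real_, J, O) else osig <- numeric(O)
  for (o in seq_len(O)) {
    obs <- which(!is.na(Z[, o]))
    W <- P[obs, , drop = FALSE]
    z <- Z[obs, o]
    wsum <- colSums(W)
    m <- as.vector(crossprod(W, z))
    mu <- ifelse(wsum > 1e-8, m / wsum,
                 if (is.null(prev)) mean(z) else prev$Mu[, o])
    Mu[, o] <- mu
    R2 <- (matrix(z, length(z), J) -
             matrix(mu, length(z), J, byrow = TRUE))^2
    if (group_var) {
      v <- colSums(W * R2) / pmax(wsum, 1e-8)
      osig[, o] <- sqrt(pmax(v, 1e-6))
    } else {
      osig[o] <- sqrt(max(sum(W * R2) / sum(wsum), 1e-6))
    }
  }
  list(Mu = Mu, osig = osig)
}

#' Per-subject joint log-likelihood contributions
#'
#' Marginal log-likelihood of each subject's trajectory observations and
#' observed distal outcomes under a fitted joint model. With no observed
#' outcomes this reduces exactly to [subject_logliks()].
#'
#' @param panel Long panel tibble.
#' @param outcomes Long outcome tibble (may contain `NA` values).
#' @param model A `joint_fit`.
#' @return Tibble with columns `subject_id`, `loglik`.
#' @export
joint_subject_logliks <- function(panel, outcomes, model) {
  bl <- panel_blocks(panel, model$scales, order = model$order,
                     center_age = model$center_age)
  ocl <- outcomes[!is.na(outcomes$value), , drop = FALSE]
  Z <- outcomes_to_matrix(ocl, bl$subjects, model$outcome_names)
  A <- cond_loglik_matrix(bl, model$beta, model$sigma) +
    outcome_cond_loglik(Z, model$Mu, osig_rows(model$outcome_sd, model$J))
  e <- estep(A, model$theta)
  tibble::tibble(subject_id = bl$subjects, loglik = e$ll_i)
}

#' Check that adding outcomes did not move the trajectory groups
#'
#' Compares model-predicted trajectory means between the trajectory-only
#' model and the joint model with outcomes, after optimal label matching
#' (so the check is invariant to label switching). The joint estimation is
#' only trusted when the groups it returns are the groups established
#' without the outcomes; this report quantifies that.
#'
#' @param before The trajectory-only `multitraj_fit`.
#' @param after The `joint_fit` (same `J`).
#' @param tol Pass threshold on the maximum absolute difference of
#'   predicted means (score units; default 1).
#' @param ages Comparison ages (default: `before`'s fitting ages).
#' @return A `stability_report`: list with `max_diff`, `pass`, `tol`,
#'   `permutation`, and `by_cell` (tibble `group`, `phenotype`, `age`,
#'   `before`, `after`, `abs_diff`).
#' @export
trajectory_stability_check <- function(before, after, tol = 1.0, ages = NULL) {
  if (before$J != after$J)
    stop("models have different numbers of groups", call. = FALSE)
  ages <- ages %||% before$ages
  ref <- predict_trajectories(before, ages)
  mm <- match_curves(curve_matrix(before, ages), curve_matrix(after, ages))
  after_aligned <- relabel_groups(after, mm$perm)
  cmp <- predict_trajectories(after_aligned, ages)
  by_cell <- dplyr::left_join(
    dplyr::rename(ref, before = "mean"),
    dplyr::rename(cmp, after = "mean"),
    by = c("group", "phenotype", "age"))
  by_cell$abs_diff <- abs(by_cell$before - by_cell$after)
  structure(
    list(max_diff = max(by_cell$abs_diff), tol = tol,
         pass = max(by_cell$abs_diff) < tol,
         permutation = mm$perm, by_cell = by_cell),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> max |predicted-mean change| = ",
      format(x$max_diff, digits = 4), " score units (tol ", x$tol, "): ",
      if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  invisible(x)
}
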