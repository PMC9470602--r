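#' Polynomial trajectory mean
#'
#' Evaluates a group's polynomial trajectory at given ages. Polynomials are
#' parameterised on centered age (`age - center_age`), so the intercept is
#' the expected score at the centering age.
#'
#' @param coeffs Numeric vector of polynomial coefficients, lowest order
#'   first (intercept, linear, quadratic, ...).
#' @param age Ages in years (vectorised).
#' @param center_age Centering constant (default 11).
#' @return Expected score(s) in scale units.
#' @examples
#' trajectory_mean(c(1, 2, 3), age = 13) # 1 + 2*2 + 3*4 = 17
#' @export
trajectory_mean <- function(coeffs, age, center_age = 11) {
  stopifnot(all(is.finite(coeffs)))
  cc <- age - center_age
  out <- numeric(length(cc))
  for (d in seq_along(coeffs)) out <- out + coeffs[d] * cc^(d - 1L)
  out
}

# ---- internal data layout ----------------------------------------------

# Reshape a long panel into per-phenotype observation blocks used by the EM
# fitter: observed scores, censoring codes, subject indices, and the
# centered-age polynomial design matrix.
panel_blocks <- function(panel, scales, order = 2L, center_age = 11) {
  stopifnot(all(c("subject_id", "age", "phenotype", "score") %in% names(panel)))
  check_scores_in_bounds(panel[!is.na(panel$score), ], scales)
  subjects <- sort(unique(panel$subject_id))
  n <- length(subjects)
  blocks <- list()
  for (ph in scales$phenotype) {
    rows <- panel$phenotype == ph & !is.na(panel$score)
    if (!any(rows)) next
    y <- panel$score[rows]
    lo <- scales$lo[scales$phenotype == ph]
    hi <- scales$hi[scales$phenotype == ph]
    cens <- integer(length(y))
    cens[y <= lo] <- -1L
    cens[y >= hi] <- 1L
    cc <- panel$age[rows] - center_age
    X <- vapply(0:order, function(d) cc^d, numeric(length(cc)))
    if (length(y) == 1L) X <- matrix(X, nrow = 1L)
    subj <- match(panel$subject_id[rows], subjects)
    blocks[[ph]] <- list(y = y, cens = cens, subj = subj, X = X,
                         lo = lo, hi = hi)
  }
  counts <- integer(n)
  for (b in blocks) counts <- counts + tabulate(b$subj, n)
  if (any(counts == 0L)) {
    cnd <- structure(
      class = c("trajmix_empty_subject", "error", "condition"),
      list(message = paste0("subjects with zero non-missing observations: ",
                            paste(head(subjects[counts == 0L], 5L), collapse = ", ")),
           call = NULL))
    stop(cnd)
  }
  list(subjects = subjects, n = n, blocks = blocks,
       ages = sort(unique(panel$age)), order = order, center_age = center_age)
}

# Per-subject, per-group trajectory log-likelihood matrix (n x J), excluding
# the membership prior.
cond_loglik_matrix <- function(bl, beta, sigma) {
  n <- bl$n
  J <- nrow(beta[[1L]])
  A <- matrix(0, n, J)
  for (k in seq_along(bl$blocks)) {
    b <- bl$blocks[[k]]
    MU <- b$X %*% t(beta[[k]])
    L <- cn_loglik_mat(b$y, b$cens, MU, sigma[k])
    S <- rowsum(L, b$subj)
    A[as.integer(rownames(S)), ] <- A[as.integer(rownames(S)), , drop = FALSE] + S
  }
  A
}

# E-step: total log-likelihood and posterior responsibilities.
estep <- function(A_cond, theta) {
  pis <- group_membership_probs(theta)
  A <- sweep(A_cond, 2L, log(pis), "+")
  ll_i <- row_logsumexp(A)
  P <- exp(A - ll_i)
  list(loglik = sum(ll_i), P = P, ll_i = ll_i)
}

# M-step for one phenotype block: responsibility-weighted censored-normal
# polynomial regression with shared sigma, by quasi-Newton ascent from the
# current parameters (a generalized M-step; ascent from a warm start keeps
# EM monotone).
mstep_phenotype <- function(b, P, beta_k, sigma_k, m_maxit = 10L) {
  J <- nrow(beta_k)
  p <- ncol(beta_k)
  W <- P[b$subj, , drop = FALSE]
  pack <- c(as.vector(beta_k), log(sigma_k))
  # keep sigma away from underflow during BFGS line searches
  sig_of <- function(par) min(max(exp(par[J * p + 1L]), 1e-6), 1e6)
  # BFGS evaluates fn and gr at the same points; evaluate the kernel once
  cache_par <- NULL
  cache_val <- NULL
  eval_kernel <- function(par) {
    if (!is.null(cache_par) && identical(par, cache_par)) return(cache_val)
    B <- matrix(par[seq_len(J * p)], J, p)
    MU <- b$X %*% t(B)
    o <- cn_weighted_obj(b$y, b$cens, MU, sig_of(par), W)
    cache_par <<- par
    cache_val <<- o
    o
  }
  fn <- function(par) {
    if (any(!is.finite(par))) return(1e12)
    v <- -eval_kernel(par)$obj
    if (!is.finite(v)) 1e12 else v
  }
  gr <- function(par) {
    if (any(!is.finite(par))) return(numeric(J * p + 1L))
    o <- eval_kernel(par)
    gB <- crossprod(b$X, o$gmu)      # p x J, d obj / d beta_j
    g <- -c(as.vector(t(gB)), o$dlsig)
    if (any(!is.finite(g))) numeric(J * p + 1L) else g
  }
  fit <- optim(pack, fn, gr, method = "BFGS",
               control = list(maxit = m_maxit))
  # guard against a pathological line-search end point: never accept a
  # parameter set worse than the warm start
  if (fit$value > fn(pack) + 1e-10)
    return(list(beta = beta_k, sigma = sigma_k))
  list(beta = matrix(fit$par[seq_len(J * p)], J, p),
       sigma = sig_of(fit$par))
}

mstep <- function(bl, P, beta, sigma, m_maxit = 10L) {
  pis <- colMeans(P)
  pis <- pmax(pis, 1e-12)
  theta <- log(pis) - log(pis[1L])
  for (k in seq_along(bl$blocks)) {
    up <- mstep_phenotype(bl$blocks[[k]], P, beta[[k]], sigma[k], m_maxit)
    beta[[k]] <- up$beta
    sigma[k] <- up$sigma
  }
  list(theta = theta, beta = beta, sigma = sigma)
}

# Weighted-least-squares parameter draw from hard/soft responsibilities,
# used to turn an initial partition into starting parameters.
params_from_responsibilities <- function(bl, P) {
  J <- ncol(P)
  K <- length(bl$blocks)
  beta <- vector("list", K)
  sigma <- numeric(K)
  for (k in seq_len(K)) {
    b <- bl$blocks[[k]]
    p <- ncol(b$X)
    W <- P[b$subj, , drop = FALSE]
    B <- matrix(0, J, p)
    rss <- 0
    for (j in seq_len(J)) {
      w <- W[, j] + 1e-8
      XtWX <- crossprod(b$X * w, b$X)
      XtWy <- crossprod(b$X * w, b$y)
      cf <- tryCatch(solve(XtWX, XtWy),
                     error = function(e) qr.solve(XtWX + diag(1e-6, p), XtWy))
      B[j, ] <- cf
      rss <- rss + sum(w * (b$y - b$X %*% cf)^2)
    }
    beta[[k]] <- B
    sigma[k] <- sqrt(rss / length(b$y))
    sigma[k] <- max(sigma[k], 1e-3)
  }
  pis <- pmax(colMeans(P), 1e-6)
  list(theta = log(pis) - log(pis[1L]), beta = beta, sigma = sigma)
}

hard_to_soft <- function(assign, J, certainty = 0.95) {
  n <- length(assign)
  P <- matrix((1 - certainty) / max(J - 1L, 1L), n, J)
  P[cbind(seq_len(n), assign)] <- if (J == 1L) 1 else certainty
  P
}

# Per-subject summary features (phenotype-wave means, standardized, missing
# set to 0) for the stratified and k-means initializations.
subject_features <- function(bl) {
  n <- bl$n
  feats <- list()
  for (k in seq_along(bl$blocks)) {
    b <- bl$blocks[[k]]
    cage <- if (ncol(b$X) >= 2L) b$X[, 2L] else rep(0, length(b$y))
    ages <- sort(unique(cage))
    F <- matrix(NA_real_, n, length(ages))
    F[cbind(b$subj, match(cage, ages))] <- b$y
    F <- scale(F)
    F[is.na(F)] <- 0
    feats[[k]] <- F
  }
  do.call(cbind, feats)
}

em_run <- function(bl, params, max_iter, tol, m_maxit = 10L) {
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  P <- NULL
  for (it in seq_len(max_iter)) {
    A <- cond_loglik_matrix(bl, params$beta, params$sigma)
    e <- estep(A, params$theta)
    trace <- c(trace, e$loglik)
    P <- e$P
    if (is.finite(ll_prev) && e$loglik - ll_prev < -1e-8)
      warning("EM log-likelihood decreased by ",
              format(ll_prev - e$loglik), call. = FALSE)
    if (is.finite(ll_prev) && abs(e$loglik - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- e$loglik
    params <- mstep(bl, P, params$beta, params$sigma, m_maxit)
  }
  list(params = params, loglik = trace[length(trace)], trace = trace,
       P = P, converged = converged, n_iter = length(trace))
}

# ---- fitting ------------------------------------------------------------

#' Fit a group-based multi-trajectory mixture model
#'
#' Maximum-likelihood estimation of a finite mixture in which each latent
#' group follows its own polynomial age trajectory on every phenotype, with
#' a censored-normal (tobit) emission honouring the scale bounds and a
#' residual SD shared across groups within each phenotype. Fitting is by EM:
#' the E-step computes posterior group responsibilities with log-sum-exp
#' stabilisation; the M-step updates membership logits in closed form and
#' performs responsibility-weighted censored-normal polynomial regression by
#' quasi-Newton ascent with analytic gradients (ascent from the current
#' parameters, so the log-likelihood never decreases).
#'
#' Several starts are tried: `n_starts` random responsibility draws, one
#' quantile-stratified start (subjects ranked by their mean standardized
#' score and cut into `J` strata), and optionally one k-means start on
#' per-subject standardized wave scores. Each start is run for `short_iter`
#' EM iterations and the best is continued to convergence. Groups that
#' collapse below one expected subject trigger a restart from a fresh random
#' initialisation.
#'
#' @param panel Long tibble with columns `subject_id`, `age`, `phenotype`,
#'   `score` (`NA` = missing). Every subject needs at least one observation.
#' @param J Number of latent groups.
#' @param order Polynomial order of the age trajectories (default 2,
#'   quadratic).
#' @param n_starts Number of random initialisations (besides the stratified
#'   and k-means starts).
#' @param seed Integer seed controlling all initialisation randomness.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations for the final run.
#' @param scales Scale specification tibble; defaults to [default_scales()]
#'   when the panel's phenotypes are covered by it.
#' @param start Optional fitted `multitraj_fit` for a warm start (skips all
#'   initialisation searches).
#' @param se If `TRUE`, compute standard errors of all parameters from the
#'   inverse observed information matrix.
#' @param short_iter EM iterations used to triage candidate starts.
#' @param m_maxit Quasi-Newton iterations per M-step.
#' @param kmeans_start Include a k-means initialisation (default `TRUE`).
#' @param center_age Age centering constant (default 11).
#'
#' @return An object of class `multitraj_fit` with, among others, `theta`
#'   (membership logits, first fixed at 0), `pi` (group proportions),
#'   `coeffs` (tibble of trajectory coefficients), `sigma` (per-phenotype
#'   residual SDs), `loglik`, `n_params`, and the EM `loglik_trace`.
#' @seealso [select_model()], [posterior_assignments()], [bic()]
#' @export
fit_multitrajectory <- function(panel, J, order = 2L, n_starts = 20L,
                                seed = 1L, tol = 1e-6, max_iter = 500L,
                                scales = NULL, start = NULL, se = FALSE,
                                short_iter = 15L, m_maxit = 6L,
                                kmeans_start = TRUE, center_age = 11) {
  stopifnot(J >= 1L, nrow(panel) > 0L)
  scales <- resolve_scales(panel, scales)
  bl <- panel_blocks(panel, scales, order = order, center_age = center_age)
  set.seed(as.integer(seed))
  n <- bl$n
  K <- length(bl$blocks)

  restarts <- 0L
  if (!is.null(start)) {
    stopifnot(inherits(start, "multitraj_fit"), start$J == J,
              start$order == order)
    best_params <- list(theta = start$theta, beta = start$beta,
                        sigma = start$sigma)
    start_logliks <- NA_real_
  } else {
    starts <- list()
    if (J == 1L) {
      starts <- list(params_from_responsibilities(bl, matrix(1, n, 1L)))
    } else {
      feats <- subject_features(bl)
      s_i <- rowMeans(feats)
      strat <- as.integer(cut(rank(s_i, ties.method = "first"),
                              breaks = J, labels = FALSE))
      starts <- c(starts, list(
        params_from_responsibilities(bl, hard_to_soft(strat, J))))
      if (isTRUE(kmeans_start)) {
        km <- tryCatch(kmeans(feats, centers = J, nstart = 3L),
                       error = function(e) NULL)
        if (!is.null(km))
          starts <- c(starts, list(
            params_from_responsibilities(bl, hard_to_soft(km$cluster, J))))
      }
      for (s in seq_len(n_starts)) {
        P0 <- matrix(rexp(n * J), n, J)
        P0 <- P0 / rowSums(P0)
        starts <- c(starts, list(params_from_responsibilities(bl, P0)))
      }
    }
    short <- lapply(starts, function(p)
      em_run(bl, p, max_iter = short_iter, tol = tol, m_maxit = m_maxit))
    start_logliks <- vapply(short, `[[`, numeric(1L), "loglik")
    best_params <- short[[which.max(start_logliks)]]$params
  }

  run <- em_run(bl, best_params, max_iter = max_iter, tol = tol,
                m_maxit = m_maxit)
  while (any(colMeans(run$P) < 1 / n) && restarts < 5L && J > 1L) {
    restarts <- restarts + 1L
    warning("group collapsed to < 1 expected subject; restarting (",
            restarts, ")", call. = FALSE)
    P0 <- matrix(rexp(n * J), n, J)
    P0 <- P0 / rowSums(P0)
    run2 <- em_run(bl, params_from_responsibilities(bl, P0),
                   max_iter = max_iter, tol = tol, m_maxit = m_maxit)
    if (run2$loglik > run$loglik || any(colMeans(run$P) < 1 / n)) run <- run2
  }
  if (!run$converged)
    warning("EM did not converge in ", max_iter,
            " iterations; returning best-so-far", call. = FALSE)

  model <- build_multitraj_fit(bl, run, J, order, scales, center_age,
                               restarts, start_logliks, seed)
  if (isTRUE(se)) model <- add_model_se(model, bl)
  model
}

resolve_scales <- function(panel, scales) {
  if (!is.null(scales)) return(scales)
  att <- attr(panel, "scales")
  if (!is.null(att)) return(att)
  def <- default_scales()
  phens <- unique(panel$phenotype)
  if (all(phens %in% def$phenotype))
    return(def[def$phenotype %in% phens, , drop = FALSE])
  stop("supply `scales` for phenotypes: ",
       paste(setdiff(phens, def$phenotype), collapse = ", "), call. = FALSE)
}

build_multitraj_fit <- function(bl, run, J, order, scales, center_age,
                                restarts, start_logliks, seed) {
  K <- length(bl$blocks)
  phens <- names(bl$blocks)
  n_params <- (J - 1L) + J * K * (order + 1L) + K
  coeffs <- purrr::map_dfr(seq_len(K), function(k) {
    B <- run$params$beta[[k]]
    out <- tibble::as_tibble(B, .name_repair = ~ paste0("b", seq_along(.x) - 1L))
    out$group <- seq_len(J)
    out$phenotype <- phens[k]
    out[, c("group", "phenotype", paste0("b", 0:order))]
  })
  structure(
    list(J = J, K = K, order = order, phenotypes = phens,
         theta = run$params$theta,
         pi = group_membership_probs(run$params$theta),
         coeffs = coeffs, beta = run$params$beta,
         sigma = setNames(run$params$sigma, phens),
         scales = scales, center_age = center_age, ages = bl$ages,
         loglik = run$loglik, n_params = n_params, n_subjects = bl$n,
         subjects = bl$subjects,
         converged = run$converged, n_iter = run$n_iter,
         loglik_trace = run$trace, restarts = restarts,
         start_logliks = start_logliks, seed = seed),
    class = "multitraj_fit")
}

#' @export
print.multitraj_fit <- function(x, ...) {
  cat("<multitraj_fit> ", x$J, " groups, ", x$K, " phenotypes, order ",
      x$order, "\n", sep = "")
  cat("  logLik ", format(x$loglik), ", ", x$n_params, " parameters, ",
      x$n_iter, " EM iterations",
      if (!x$converged) " (not converged)", "\n", sep = "")
  cat("  proportions:", paste(sprintf("%.3f", x$pi), collapse = ", "), "\n")
  invisible(x)
}

#' Model-predicted trajectory means
#'
#' @param model A `multitraj_fit` or `joint_fit`.
#' @param ages Ages at which to evaluate (defaults to the ages seen when
#'   fitting).
#' @return Tibble with columns `group`, `phenotype`, `age`, `mean`.
#' @export
predict_trajectories <- function(model, ages = NULL) {
  ages <- ages %||% model$ages
  grid <- tidyr::expand_grid(group = seq_len(model$J),
                             phenotype = model$phenotypes, age = ages)
  cf <- model$coeffs
  idx <- match(paste(grid$group, grid$phenotype),
               paste(cf$group, cf$phenotype))
  bcols <- grep("^b[0-9]+$", names(cf), value = TRUE)
  B <- as.matrix(cf[idx, bcols])
  cc <- grid$age - model$center_age
  grid$mean <- rowSums(B * outer(cc, seq_along(bcols) - 1L, `^`))
  grid
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-subject mixture log-likelihood contributions
#'
#' The marginal log-likelihood of each subject's observed trajectory data
#' under a fitted model: `log sum_j pi_j exp(l_ij)` computed with
#' log-sum-exp stabilisation, where `l_ij` sums the censored-normal log
#' densities of the subject's non-missing observations under group `j`.
#' Missing observations contribute nothing.
#'
#' @param panel Long panel tibble.
#' @param model A `multitraj_fit`.
#' @return Tibble with columns `subject_id`, `loglik`.
#' @export
subject_logliks <- function(panel, model) {
  bl <- panel_blocks(panel, model$scales, order = model$order,
                     center_age = model$center_age)
  A <- cond_loglik_matrix(bl, model$beta, model$sigma)
  e <- estep(A, model$theta)
  tibble::tibble(subject_id = bl$subjects, loglik = e$ll_i)
}

#' Posterior group assignments
#'
#' Bayes-rule posterior membership probabilities for every subject under a
#' fitted model, the modal assignment (ties broken toward the lowest group
#' index), and the per-group average posterior probability (APP) among
#' modally assigned subjects - the standard class-separation diagnostic.
#'
#' @param panel Long panel tibble.
#' @param model A `multitraj_fit`.
#' @return Tibble with columns `subject_id`, `modal`, `p_modal`, and one
#'   `p_<j>` column per group. The APP table (columns `group`, `n_modal`,
#'   `app`) is attached as attribute `"app"`; see [average_posterior_prob()].
#' @export
posterior_assignments <- function(panel, model) {
  bl <- panel_blocks(panel, model$scales, order = model$order,
                     center_age = model$center_age)
  A <- cond_loglik_matrix(bl, model$beta, model$sigma)
  e <- estep(A, model$theta)
  P <- e$P
  modal <- max.col(P, ties.method = "first")
  out <- tibble::tibble(subject_id = bl$subjects, modal = modal,
                        p_modal = P[cbind(seq_len(nrow(P)), modal)])
  probs <- tibble::as_tibble(P, .name_repair = ~ paste0("p_", seq_len(model$J)))
  out <- dplyr::bind_cols(out, probs)
  app <- tibble::tibble(
    group = seq_len(model$J),
    n_modal = vapply(seq_len(model$J), function(j) sum(modal == j), integer(1L)),
    app = vapply(seq_len(model$J), function(j) {
      if (any(modal == j)) mean(P[modal == j, j]) else NA_real_
    }, numeric(1L)))
  attr(out, "app") <- app
  out
}

#' Average posterior probability by group
#'
#' @param assignments Output of [posterior_assignments()].
#' @return Tibble with columns `group`, `n_modal`, `app`.
#' @export
average_posterior_prob <- function(assignments) {
  attr(assignments, "app")
}

#' Bayesian information criterion
#'
#' `-2 logLik + n_params log(n)`; lower is better. (The equivalent
#' maximisation convention `2(logLik - 0.5 k log n)` orders models
#' identically.)
#'
#' @param model A fitted `multitraj_fit` or `joint_fit`.
#' @param n Sample size (defaults to the number of subjects used in
#'   fitting).
#' @return The BIC value.
#' @export
bic <- function(model, n = model$n_subjects) {
  -2 * model$loglik + model$n_params * log(n)
}

#' Fit a series of models and select the number of groups
#'
#' Fits the multi-trajectory model for each candidate number of groups and
#' tabulates log-likelihood, BIC and the smallest group share. The chosen
#' model minimises BIC, but candidates containing groups smaller than
#' `min_share` are flagged: information criteria alone should not settle the
#' choice when a "better" model buys its fit with vanishingly small groups.
#'
#' @param panel Long panel tibble.
#' @param J_range Integer vector of candidate group counts.
#' @param order Polynomial order.
#' @param seed Integer seed (each candidate derives its own seed from it).
#' @param min_share Practical lower bound on an acceptable group share.
#' @param keep_fits Keep the fitted models in the result (attribute
#'   `"fits"`).
#' @param ... Passed to [fit_multitrajectory()].
#' @return A tibble (class `model_selection`) with one row per candidate:
#'   `J`, `loglik`, `n_params`, `bic`, `min_share`, `converged`,
#'   `small_group`, `error`. The selected `J` is attached as attribute
#'   `"chosen_J"`.
#' @export
select_model <- function(panel, J_range, order = 2L, seed = 1L,
                         min_share = 0.05, keep_fits = FALSE, ...) {
  stopifnot(length(J_range) >= 1L)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(2^31 - 2, length(J_range))
  fits <- vector("list", length(J_range))
  rows <- purrr::map_dfr(seq_along(J_range), function(i) {
    J <- J_range[i]
    fit <- tryCatch(
      fit_multitrajectory(panel, J, order = order, seed = sub_seeds[i], ...),
      error = function(e) e)
    if (inherits(fit, "error"))
      return(tibble::tibble(J = J, loglik = NA_real_, n_params = NA_integer_,
                            bic = NA_real_, min_share = NA_real_,
                            converged = NA, small_group = NA,
                            error = conditionMessage(fit)))
    fits[[i]] <<- fit
    tibble::tibble(J = J, loglik = fit$loglik, n_params = fit$n_params,
                   bic = bic(fit), min_share = min(fit$pi),
                   converged = fit$converged,
                   small_group = min(fit$pi) < min_share,
                   error = NA_character_)
  })
  ok <- which(!is.na(rows$bic))
  chosen <- if (length(ok)) rows$J[ok[which.min(rows$bic[ok])]] else NA_integer_
  out <- structure(rows, class = c("model_selection", class(rows)),
                   chosen_J = chosen, min_share_threshold = min_share)
  if (keep_fits) attr(out, "fits") <- fits
  out
}

#' @export
print.model_selection <- function(x, ...) {
  NextMethod()
  cat("Chosen J (minimum BIC):", attr(x, "chosen_J"), "\n")
  if (any(x$small_group %in% TRUE))
    cat("Note: flagged candidates contain a group below share ",
        attr(x, "min_share_threshold"), "\n", sep = "")
  invisible(x)
}
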