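# Analytic observed-data score and observed information for the mixture
# model, with or without the distal-outcome block. Standard errors are the
# square roots of the diagonal of the inverse observed information; the
# information matrix itself is the negative Jacobian of the analytic score,
# obtained by central differences (exact derivatives of the score, so the
# Hessian is accurate to O(h^2) without differencing the log-likelihood
# twice).

param_dims <- function(J, K, p, O = 0L) {
  sizes <- c(eta = J - 1L, beta = J * p * K, logsig = K,
             omu = J * O, ologsig = O)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  list(J = J, K = K, p = p, O = O, sizes = sizes,
       idx = purrr::map2(starts, ends, function(s, e)
         if (e >= s) seq(s, e) else integer(0)))
}

pack_params <- function(theta, beta, sigma, Mu = NULL, osig = NULL) {
  c(theta[-1L], unlist(lapply(beta, as.vector)), log(sigma),
    if (!is.null(Mu)) as.vector(Mu), if (!is.null(osig)) log(osig))
}

unpack_params <- function(par, d) {
  theta <- c(0, par[d$idx$eta])
  bvec <- par[d$idx$beta]
  beta <- lapply(seq_len(d$K), function(k) {
    matrix(bvec[((k - 1L) * d$J * d$p + 1L):(k * d$J * d$p)], d$J, d$p)
  })
  sigma <- exp(par[d$idx$logsig])
  out <- list(theta = theta, beta = beta, sigma = sigma)
  if (d$O > 0L) {
    out$Mu <- matrix(par[d$idx$omu], d$J, d$O)
    out$osig <- exp(par[d$idx$ologsig])
  }
  out
}

# n x J log-likelihood contribution of observed outcomes per group.
# `osig` is either a length-O vector (variance shared across groups) or a
# J x O matrix (group-specific variances).
outcome_cond_loglik <- function(Z, Mu, osig) {
  n <- nrow(Z); J <- nrow(Mu)
  S <- if (is.matrix(osig)) osig else
    matrix(osig, J, length(osig), byrow = TRUE)
  A <- matrix(0, n, J)
  for (o in seq_len(ncol(Z))) {
    obs <- which(!is.na(Z[, o]))
    if (!length(obs)) next
    ZM <- matrix(Z[obs, o], length(obs), J)
    M <- matrix(Mu[, o], length(obs), J, byrow = TRUE)
    SD <- matrix(S[, o], length(obs), J, byrow = TRUE)
    A[obs, ] <- A[obs, ] + dnorm(ZM, M, SD, log = TRUE)
  }
  A
}

# Total log-likelihood and analytic score at packed parameters.
joint_loglik_score <- function(par, d, bl, Z = NULL, loglik_only = FALSE) {
  pr <- unpack_params(par, d)
  A <- cond_loglik_matrix(bl, pr$beta, pr$sigma)
  if (d$O > 0L) A <- A + outcome_cond_loglik(Z, pr$Mu, pr$osig)
  e <- estep(A, pr$theta)
  if (loglik_only) return(e$loglik)
  P <- e$P
  pis <- group_membership_probs(pr$theta)
  g <- numeric(length(par))
  if (d$J > 1L)
    g[d$idx$eta] <- colSums(P)[-1L] - bl$n * pis[-1L]
  gb <- numeric(0)
  for (k in seq_len(d$K)) {
    b <- bl$blocks[[k]]
    MU <- b$X %*% t(pr$beta[[k]])
    G <- cn_grad_mat(b$y, b$cens, MU, pr$sigma[k])
    W <- P[b$subj, , drop = FALSE]
    dB <- crossprod(b$X, W * G$gmu)            # p x J
    gb <- c(gb, as.vector(t(dB)))
    g[d$idx$logsig][k] <- sum(W * G$glsig)
  }
  g[d$idx$beta] <- gb
  if (d$O > 0L) {
    dMu <- matrix(0, d$J, d$O)
    dls <- numeric(d$O)
    for (o in seq_len(d$O)) {
      obs <- which(!is.na(Z[, o]))
      if (!length(obs)) next
      ZM <- matrix(Z[obs, o], length(obs), d$J)
      M <- matrix(pr$Mu[, o], length(obs), d$J, byrow = TRUE)
      R <- ZM - M
      W <- P[obs, , drop = FALSE]
      dMu[, o] <- colSums(W * R) / pr$osig[o]^2
      dls[o] <- sum(W * (R^2 / pr$osig[o]^2 - 1))
    }
    g[d$idx$omu] <- as.vector(dMu)
    g[d$idx$ologsig] <- dls
  }
  list(loglik = e$loglik, score = g)
}

observed_information <- function(par, score_fn, h_rel = 1e-5) {
  p <- length(par)
  Jac <- matrix(0, p, p)
  for (i in seq_len(p)) {
    h <- h_rel * max(1, abs(par[i]))
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    Jac[, i] <- (score_fn(up) - score_fn(dn)) / (2 * h)
  }
  -(Jac + t(Jac)) / 2
}

# Inverse-information SEs; returns list(se, ok). Delta method converts the
# log-scale SD entries back to the SD scale.
se_from_information <- function(info, par, d) {
  V <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  if (is.null(V) || any(diag(V) <= 0))
    return(list(se = rep(NA_real_, length(par)), ok = FALSE))
  se <- sqrt(diag(V))
  se[d$idx$logsig] <- se[d$idx$logsig] * exp(par[d$idx$logsig])
  if (d$O > 0L)
    se[d$idx$ologsig] <- se[d$idx$ologsig] * exp(par[d$idx$ologsig])
  list(se = se, ok = TRUE)
}

# Attach SEs (membership logits, trajectory coefficients, residual SDs) to a
# fitted multi-trajectory model.
add_model_se <- function(model, bl) {
  d <- param_dims(model$J, model$K, model$order + 1L)
  par <- pack_params(model$theta, model$beta, model$sigma)
  info <- observed_information(par, function(p)
    joint_loglik_score(p, d, bl)$score)
  se <- se_from_information(info, par, d)
  model$se_ok <- se$ok
  if (se$ok) {
    bse <- se$se[d$idx$beta]
    se_tbl <- purrr::map_dfr(seq_len(model$K), function(k) {
      S <- matrix(bse[((k - 1L) * model$J * d$p + 1L):(k * model$J * d$p)],
                  model$J, d$p)
      out <- tibble::as_tibble(S, .name_repair = ~ paste0("se_b", seq_along(.x) - 1L))
      out$group <- seq_len(model$J)
      out$phenotype <- model$phenotypes[k]
      out
    })
    model$coeffs <- dplyr::left_join(model$coeffs, se_tbl,
                                     by = c("group", "phenotype"))
    model$sigma_se <- setNames(se$se[d$idx$logsig], model$phenotypes)
    model$theta_se <- c(0, se$se[d$idx$eta])
  }
  model
}
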