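#' Multiple imputation by chained equations
#'
#' Fills missing cells `M` times by fully conditional specification:
#' within each imputed dataset the variables are visited in turn for
#' `n_iter` sweeps, each conditional model regressing the variable on all
#' other variables of the (current) completed data. Continuous variables
#' use predictive mean matching: a Bayesian draw of the linear-regression
#' coefficients produces predicted means, and each missing cell receives
#' the observed value of one of its `k_donors` nearest predicted-mean
#' donors, chosen uniformly at random - so imputed values always belong to
#' the variable's observed support. Factor variables use a polytomous
#' (multinomial-logit) model with a categorical draw from the predicted
#' probabilities. Perfectly collinear predictors trigger a ridge fallback
#' with a warning.
#'
#' @param data Data frame / tibble with missing cells. Numeric columns are
#'   imputed by PMM, factors by polytomous regression; columns named in
#'   `id_cols` are carried through untouched and excluded from the
#'   conditional models.
#' @param M Number of imputations (>= 2).
#' @param n_iter Chained-equation sweeps per imputation.
#' @param k_donors Donor-pool size for PMM.
#' @param seed Master seed; each imputation derives an independent seed.
#' @param id_cols Identifier columns excluded from modelling (default:
#'   `"subject_id"` when present).
#'
#' @return Object of class `imputation_set`: list with `M`, `completed`
#'   (list of `M` completed tibbles), `seed`, `imp_seeds`, and `trace`, a
#'   tibble (`m`, `iter`, `variable`, `mean_imputed`) of per-sweep means of
#'   the imputed values for convergence inspection.
#' @export
chained_impute <- function(data, M = 3L, n_iter = 10L, k_donors = 5L,
                           seed = 1L,
                           id_cols = intersect("subject_id", names(data))) {
  data <- tibble::as_tibble(data)
  if (M < 2L) stop("at least two imputations are required", call. = FALSE)
  vars <- setdiff(names(data), id_cols)
  for (v in vars) {
    if (!is.numeric(data[[v]]) && !is.factor(data[[v]]))
      stop("column `", v, "` must be numeric or factor", call. = FALSE)
    n_obs <- sum(!is.na(data[[v]]))
    if (anyNA(data[[v]]) && n_obs < k_donors)
      stop("column `", v, "` has fewer than k_donors observed values",
           call. = FALSE)
    if (n_obs == 0L)
      stop("column `", v, "` is entirely missing", call. = FALSE)
  }
  set.seed(as.integer(seed))
  imp_seeds <- sample.int(2^31 - 2, M)
  has_na <- vars[vapply(vars, function(v) anyNA(data[[v]]), logical(1L))]
  completed <- vector("list", M)
  trace <- list()
  for (m in seq_len(M)) {
    set.seed(imp_seeds[m])
    cur <- data
    # initial fill: random draws from each variable's observed values
    for (v in has_na) {
      miss <- is.na(cur[[v]])
      obs <- cur[[v]][!miss]
      cur[[v]][miss] <- sample(obs, sum(miss), replace = TRUE)
    }
    if (length(has_na)) {
      for (it in seq_len(n_iter)) {
        for (v in has_na) {
          miss <- is.na(data[[v]])
          imp <- impute_one(cur, v, miss, vars, k_donors)
          cur[[v]][miss] <- imp
          trace[[length(trace) + 1L]] <- tibble::tibble(
            m = m, iter = it, variable = v,
            mean_imputed = if (is.numeric(imp)) mean(imp) else
              mean(as.numeric(imp)))
        }
      }
    }
    completed[[m]] <- cur
  }
  structure(
    list(M = M, completed = completed, seed = seed, imp_seeds = imp_seeds,
         n_iter = n_iter, k_donors = k_donors,
         trace = if (length(trace)) dplyr::bind_rows(trace) else
           tibble::tibble(m = integer(0), iter = integer(0),
                          variable = character(0), mean_imputed = numeric(0))),
    class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set> M =", x$M, "imputations,", x$n_iter,
      "chained sweeps, PMM with", x$k_donors, "donors\n")
  invisible(x)
}

# One conditional-model update of variable v given all others.
impute_one <- function(cur, v, miss, vars, k_donors) {
  preds <- setdiff(vars, v)
  X <- stats::model.matrix(~ ., data = cur[, preds, drop = FALSE])
  y <- cur[[v]]
  if (is.factor(y)) {
    df <- as.data.frame(X[, -1L, drop = FALSE])  # drop intercept, multinom adds its own
    names(df) <- paste0("x", seq_along(df))
    df$.y <- y
    fit <- nnet::multinom(.y ~ ., data = df[!miss, , drop = FALSE],
                          trace = FALSE, MaxNWts = 5000)
    pr <- stats::predict(fit, newdata = df[miss, , drop = FALSE],
                         type = "probs")
    lev <- levels(y)
    if (is.null(dim(pr))) {
      # two-level response: probability of the second level
      pr <- cbind(1 - pr, pr)
    }
    draws <- apply(pr, 1L, function(p) sample(lev, 1L, prob = p))
    return(factor(draws, levels = lev))
  }
  pmm_draw(X, y, miss, k_donors)
}

# Bayesian-draw linear regression + predictive mean matching.
pmm_draw <- function(X, y, miss, k_donors) {
  Xo <- X[!miss, , drop = FALSE]
  yo <- y[!miss]
  p <- ncol(X)
  XtX <- crossprod(Xo)
  Xty <- crossprod(Xo, yo)
  qrX <- qr(Xo)
  ridge <- 0
  if (qrX$rank < p) {
    ridge <- 1e-5 * mean(diag(XtX))
    warning("collinear predictors when imputing; applying ridge penalty",
            call. = FALSE)
  }
  Ai <- solve(XtX + diag(ridge + 1e-10, p))
  betahat <- Ai %*% Xty
  res <- yo - Xo %*% betahat
  df <- max(length(yo) - qrX$rank, 1L)
  sigma2 <- sum(res^2) / rchisq(1L, df)
  Rc <- chol(Ai)
  betastar <- betahat + sqrt(sigma2) * crossprod(Rc, rnorm(p))
  yhat_obs <- drop(Xo %*% betahat)
  yhat_mis <- drop(X[miss, , drop = FALSE] %*% betastar)
  vapply(yhat_mis, function(yh) {
    d <- abs(yhat_obs - yh)
    donors <- order(d)[seq_len(min(k_donors, length(d)))]
    yo[donors[sample.int(length(donors), 1L)]]
  }, numeric(1L))
}
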