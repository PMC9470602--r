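#' Censored-normal (tobit) log density
#'
#' Log-likelihood of an observed bounded score under a normal latent variable
#' censored at the scale bounds: scores at `lo` contribute the lower-tail
#' mass `log P(Y* <= lo)`, scores at `hi` the upper-tail mass, and interior
#' scores the ordinary normal log density. With infinite bounds this reduces
#' exactly to `dnorm(..., log = TRUE)`.
#'
#' @param y Observed score(s); must lie in `[lo, hi]`.
#' @param mu Latent mean(s) (recycled against `y`).
#' @param sigma Residual standard deviation, a single positive number.
#' @param lo,hi Censoring bounds (scale minimum/maximum).
#'
#' @return Numeric vector of log densities / log masses.
#' @examples
#' censored_normal_loglik(20, mu = 20, sigma = 1, lo = 7, hi = 35) # log(1/sqrt(2*pi))
#' censored_normal_loglik(7, mu = 7, sigma = 3, lo = 7, hi = 35)   # log(0.5)
#' @export
censored_normal_loglik <- function(y, mu, sigma, lo, hi) {
  stopifnot(length(sigma) == 1L, is.finite(sigma), sigma > 0,
            length(lo) == 1L, length(hi) == 1L, lo < hi)
  n <- max(length(y), length(mu))
  y <- rep_len(as.numeric(y), n)
  mu <- rep_len(as.numeric(mu), n)
  if (any(!is.finite(y)))
    stop("y must be finite", call. = FALSE)
  if (any(y < lo | y > hi))
    stop("y outside censoring bounds [", lo, ", ", hi, "]", call. = FALSE)
  cens <- integer(n)
  cens[y <= lo] <- -1L
  cens[y >= hi] <- 1L
  drop(cn_loglik_mat(y, cens, matrix(mu, ncol = 1L), sigma))
}

#' Group-membership probabilities from logits
#'
#' Softmax transform of group-membership logits. The first logit is
#' conventionally fixed at zero for identification; the transform is
#' invariant to adding a constant to all logits.
#'
#' @param theta Numeric vector of logits (length = number of groups).
#' @return Probability vector summing to 1.
#' @examples
#' group_membership_probs(c(0, 0, 0))
#' group_membership_probs(c(log(2), 0))
#' @export
group_membership_probs <- function(theta) {
  stopifnot(all(is.finite(theta)))
  e <- exp(theta - max(theta))
  e / sum(e)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise log-sum-exp of a matrix
row_logsumexp <- function(a) {
  m <- apply(a, 1L, max)
  m + log(rowSums(exp(a - m)))
}
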