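#include <Rcpp.h>
using namespace Rcpp;

// Censored (tobit) normal log-likelihood kernels shared by the EM fitter.
// cens codes: -1 observation at the lower bound, 0 interior, +1 upper bound.

static const double LOG_SQRT_2PI = 0.9189385332046727;

// log density / boundary mass for one (y, mu) pair
static inline double cn_ll(double y, int cens, double mu, double sigma) {
  if (cens == 0) {
    double z = (y - mu) / sigma;
    return -std::log(sigma) - LOG_SQRT_2PI - 0.5 * z * z;
  } else if (cens < 0) {
    double a = (y - mu) / sigma;
    return R::pnorm(a, 0.0, 1.0, 1, 1);
  } else {
    double b = (y - mu) / sigma;
    return R::pnorm(b, 0.0, 1.0, 0, 1);
  }
}

// [[Rcpp::export]]
NumericMatrix cn_loglik_mat(NumericVector y, IntegerVector cens,
                            NumericMatrix mu, double sigma) {
  int n = y.size(), J = mu.ncol();
  if (mu.nrow() != n) stop("mu must have one row per observation");
  if (sigma <= 0) stop("sigma must be positive");
  NumericMatrix out(n, J);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < n; ++i)
      out(i, j) = cn_ll(y[i], cens[i], mu(i, j), sigma);
  return out;
}

// Weighted objective + gradient for the M-step: given per-observation,
// per-group weights W (posterior responsibilities expanded to observations),
// returns sum(W * ll), the weighted d ll / d mu matrix, and the scalar
// d ll / d log(sigma).
// [[Rcpp::export]]
List cn_weighted_obj(NumericVector y, IntegerVector cens,
                     NumericMatrix mu, double sigma, NumericMatrix W) {
  int n = y.size(), J = mu.ncol();
  if (sigma <= 0) stop("sigma must be positive");
  NumericMatrix gmu(n, J);
  double obj = 0.0, dlsig = 0.0;
  for (int j = 0; j < J; ++j) {
    for (int i = 0; i < n; ++i) {
      double w = W(i, j);
      double m = mu(i, j);
      int c = cens[i];
      double ll, dm, dls;
      if (c == 0) {
        double z = (y[i] - m) / sigma;
        ll = -std::log(sigma) - LOG_SQRT_2PI - 0.5 * z * z;
        dm = z / sigma;
        dls = z * z - 1.0;
      } else if (c < 0) {
        double a = (y[i] - m) / sigma;
        ll = R::pnorm(a, 0.0, 1.0, 1, 1);
        // inverse Mills ratio phi(a)/Phi(a), computed on the log scale
        double mills = std::exp(R::dnorm(a, 0.0, 1.0, 1) - ll);
        dm = -mills / sigma;
        dls = -a * mills;
      } else {
        double b = (y[i] - m) / sigma;
        ll = R::pnorm(b, 0.0, 1.0, 0, 1);
        double mills = std::exp(R::dnorm(b, 0.0, 1.0, 1) - ll);
        dm = mills / sigma;
        dls = b * mills;
      }
      obj += w * ll;
      gmu(i, j) = w * dm;
      dlsig += w * dls;
    }
  }
  return List::create(_["obj"] = obj, _["gmu"] = gmu, _["dlsig"] = dlsig);
}

// Per-observation gradient components (unweighted), used when assembling
// analytic score vectors for the observed information matrix.
// [[Rcpp::export]]
List cn_grad_mat(NumericVector y, IntegerVector cens,
                 NumericMatrix mu, double sigma) {
  int n = y.size(), J = mu.ncol();
  NumericMatrix gmu(n, J), glsig(n, J);
  for (int j = 0; j < J; ++j) {
    for (int i = 0; i < n; ++i) {
      double m = mu(i, j);
      int c = cens[i];
      if (c == 0) {
        double z = (y[i] - m) / sigma;
        gmu(i, j) = z / sigma;
        glsig(i, j) = z * z - 1.0;
      } else if (c < 0) {
        double a = (y[i] - m) / sigma;
        double mills = std::exp(R::dnorm(a, 0.0, 1.0, 1) -
                                R::pnorm(a, 0.0, 1.0, 1, 1));
        gmu(i, j) = -mills / sigma;
        glsig(i, j) = -a * mills;
      } else {
        double b = (y[i] - m) / sigma;
        double mills = std::exp(R::dnorm(b, 0.0, 1.0, 1) -
                                R::pnorm(b, 0.0, 1.0, 0, 1));
        gmu(i, j) = mills / sigma;
        glsig(i, j) = b * mills;
      }
    }
  }
  return List::create(_["gmu"] = gmu, _["glsig"] = glsig);
}
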