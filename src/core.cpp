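#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Log-sum-exp over a vector, guarded against all -Inf.
static double lse(const arma::vec &v) {
  double m = v.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(arma::accu(arma::exp(v - m)));
}

// Forward filtering / backward sampling for an HMM with per-frame
// log-likelihood matrix `loglik` (T x K), log transition matrix `logpi`
// (K x K, rows are log of stochastic rows) and log initial weights
// `logpi0` (K). Messages are kept in log space with per-frame
// normalization so underflow cannot occur for any T. Draws one label
// sequence from the exact conditional posterior using R's RNG.
// Returns 0-based labels of length T.
// [[Rcpp::export]]
arma::ivec ffbs_sample(const arma::mat &logpi, const arma::vec &logpi0,
                       const arma::mat &loglik) {
  const int T = loglik.n_rows, K = loglik.n_cols;
  arma::mat alpha(T, K);

  alpha.row(0) = (logpi0.t() + loglik.row(0));
  alpha.row(0) -= lse(alpha.row(0).t());
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      arma::vec prev = alpha.row(t - 1).t() + logpi.col(k);
      alpha(t, k) = lse(prev) + loglik(t, k);
    }
    double norm = lse(alpha.row(t).t());
    if (!std::isfinite(norm))
      stop("non-finite forward message at frame %d", t + 1);
    alpha.row(t) -= norm;
  }

  arma::ivec z(T);
  // sample z_{T-1} from normalized alpha
  {
    arma::vec p = arma::exp(alpha.row(T - 1).t());
    p /= arma::accu(p);
    double u = R::unif_rand(), c = 0.0;
    int k = K - 1;
    for (int j = 0; j < K; ++j) { c += p(j); if (u <= c) { k = j; break; } }
    z(T - 1) = k;
  }
  for (int t = T - 2; t >= 0; --t) {
    arma::vec lp = alpha.row(t).t() + logpi.col(z(t + 1));
    lp -= lse(lp);
    arma::vec p = arma::exp(lp);
    p /= arma::accu(p);
    double u = R::unif_rand(), c = 0.0;
    int k = K - 1;
    for (int j = 0; j < K; ++j) { c += p(j); if (u <= c) { k = j; break; } }
    z(t) = k;
  }
  return z;
}

// Log marginal likelihood of the observations with labels summed out,
// by the forward algorithm in log space (same message convention as
// ffbs_sample).
// [[Rcpp::export]]
double forward_loglik(const arma::mat &logpi, const arma::vec &logpi0,
                      const arma::mat &loglik) {
  const int T = loglik.n_rows, K = loglik.n_cols;
  arma::vec a = logpi0 + loglik.row(0).t();
  double total = lse(a);
  if (!std::isfinite(total)) stop("non-finite forward message at frame 1");
  a -= total;
  for (int t = 1; t < T; ++t) {
    arma::vec nxt(K);
    for (int k = 0; k < K; ++k) nxt(k) = lse(a + logpi.col(k)) + loglik(t, k);
    double norm = lse(nxt);
    if (!std::isfinite(norm))
      stop("non-finite forward message at frame %d", t + 1);
    total += norm;
    a = nxt - norm;
  }
  return total;
}

// 8-connected component labeling of a logical mask (flood fill).
// Returns an integer matrix of the same shape: 0 = background,
// 1..n = component id.
// [[Rcpp::export]]
IntegerMatrix label_components(const LogicalMatrix &mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> stack;
  int comp = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++comp;
      stack.clear();
      stack.emplace_back(i, j);
      lab(i, j) = comp;
      while (!stack.empty()) {
        auto [r, c] = stack.back();
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = comp;
              stack.emplace_back(rr, cc);
            }
          }
        }
      }
    }
  }
  return lab;
}
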