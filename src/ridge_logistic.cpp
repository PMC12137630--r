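// L2-penalised logistic regression by damped Newton/IRLS.
// Penalty: (lambda/2) * ||w||^2 on the weights; intercept unpenalised.
// Solved in the primal when p <= n, else in the dual (w = X'a), which is
// exact for the L2 penalty since the minimiser lies in the row span of X.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline vec sigmoid(const vec& z) {
  return 1.0 / (1.0 + exp(-z));
}

static double objective(const vec& eta, const vec& y, double lambda,
                        double wnorm2) {
  // -loglik + lambda/2 ||w||^2, computed stably
  vec ll = -y % eta + log1p(exp(-abs(eta))) + max(eta, zeros(eta.n_elem));
  return accu(ll) + 0.5 * lambda * wnorm2;
}

// [[Rcpp::export]]
Rcpp::List ridge_logistic_fit_cpp(const arma::mat& X, const arma::vec& y,
                                  double lambda, double tol, int max_iter) {
  const uword n = X.n_rows, p = X.n_cols;
  bool primal = (p <= n);
  bool converged = false;
  int it = 0;

  if (primal) {
    vec theta(p + 1, fill::zeros);            // [w; b0]
    mat Z = join_rows(X, ones(n, 1));
    vec dpen(p + 1, fill::value(lambda));
    dpen(p) = 0.0;
    double f = objective(Z * theta, y, lambda, 0.0);
    for (it = 0; it < max_iter; ++it) {
      vec eta = Z * theta;
      vec mu = sigmoid(eta);
      vec g = Z.t() * (mu - y) + dpen % theta;
      if (norm(g, "inf") < tol) { converged = true; break; }
      vec w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
      mat H = Z.t() * (Z.each_col() % w);
      H.diag() += dpen + 1e-12;
      vec step = solve(H, g, solve_opts::likely_sympd);
      double s = 1.0;
      for (int h = 0; h < 30; ++h) {        // step halving
        vec cand = theta - s * step;
        double fc = objective(Z * cand, y, lambda,
                              dot(cand.head(p), cand.head(p)));
        if (fc <= f + 1e-12) { theta = cand; f = fc; break; }
        s *= 0.5;
      }
    }
    return Rcpp::List::create(
      Rcpp::Named("coef") = theta.head(p),
      Rcpp::Named("intercept") = theta(p),
      Rcpp::Named("converged") = converged,
      Rcpp::Named("iterations") = it);
  }

  // dual: eta = K a + b0, w = X'a, ||w||^2 = a'Ka
  mat K = X * X.t();
  vec a(n, fill::zeros);
  double b0 = 0.0;
  double f = objective(zeros(n) + b0, y, lambda, 0.0);
  for (it = 0; it < max_iter; ++it) {
    vec eta = K * a + b0;
    vec mu = sigmoid(eta);
    vec ga = K * ((mu - y) + lambda * a);
    double gb = accu(mu - y);
    if (std::max(norm(ga, "inf"), std::abs(gb)) < tol) {
      converged = true; break;
    }
    vec w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
    mat KW = K.each_col() % w;               // diag(w) * K, row-scaled
    mat H(n + 1, n + 1);
    H.submat(0, 0, n - 1, n - 1) = K * KW + lambda * K;
    H.submat(0, n, n - 1, n) = K * w;
    H.submat(n, 0, n, n - 1) = (w.t() * K);
    H(n, n) = accu(w);
    H.diag() += 1e-10 * (1.0 + trace(K) / n);
    vec g(n + 1);
    g.head(n) = ga;
    g(n) = gb;
    vec step = solve(H, g);
    double s = 1.0;
    for (int h = 0; h < 30; ++h) {
      vec ac = a - s * step.head(n);
      double bc = b0 - s * step(n);
      double fc = objective(K * ac + bc, y, lambda,
                            as_scalar(ac.t() * K * ac));
      if (fc <= f + 1e-12) { a = ac; b0 = bc; f = fc; break; }
      s *= 0.5;
    }
  }
  vec w = X.t() * a;
  return Rcpp::List::create(
    Rcpp::Named("coef") = w,
    Rcpp::Named("intercept") = b0,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = it);
}
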