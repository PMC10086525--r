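// Per-feature negative-binomial GLM fitting with log link and fixed
// per-feature dispersion, via iteratively reweighted least squares.
// The design matrix is shared across features, which is what makes a
// tight compiled loop worthwhile for thousands of genes/peaks.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// NB variance function: V(mu) = mu + phi * mu^2 (phi = 0 gives Poisson).
// [[Rcpp::export]]
List fit_nb_glm_cpp(const arma::mat& Y,       // features x samples
                    const arma::mat& X,       // samples x p design
                    const arma::vec& offset,  // length n, log scale
                    const arma::vec& phi,     // length G dispersions
                    int maxit = 50,
                    double tol = 1e-10) {
  const arma::uword G = Y.n_rows, n = Y.n_cols, p = X.n_cols;
  arma::mat beta(G, p, arma::fill::zeros);
  arma::mat se(G, p, arma::fill::zeros);
  arma::mat Mu(G, n, arma::fill::zeros);
  LogicalVector converged(G);

  for (arma::uword g = 0; g < G; ++g) {
    arma::rowvec y = Y.row(g);
    double ph = phi(g);
    // initialise at the intercept-only fit on the offset scale
    arma::vec b(p, arma::fill::zeros);
    double ybar = arma::mean(y % arma::exp(-offset.t()));
    b(0) = std::log(std::max(ybar, 1e-8));
    arma::vec eta = X * b + offset;
    arma::vec mu = arma::exp(eta);
    bool ok = false;
    double dev_old = arma::datum::inf;
    arma::mat XtWX(p, p);
    for (int it = 0; it < maxit; ++it) {
      // working weights w = mu^2 / V(mu); working response z
      arma::vec V = mu + ph * arma::square(mu);
      arma::vec w = arma::square(mu) / V;
      arma::vec z = (eta - offset) + (y.t() - mu) / mu;
      arma::mat Xw = X.each_col() % w;
      XtWX = X.t() * Xw;
      arma::vec XtWz = Xw.t() * z;
      arma::vec b_new;
      bool solved = arma::solve(b_new, XtWX, XtWz,
                                arma::solve_opts::no_approx);
      if (!solved || !b_new.is_finite()) { ok = false; break; }
      b = b_new;
      eta = X * b + offset;
      // guard against overflow in exp()
      eta.transform([](double e) {
        return std::min(std::max(e, -50.0), 50.0);
      });
      mu = arma::exp(eta);
      // NB deviance-free convergence check on the weighted objective
      double dev = 0.0;
      for (arma::uword s = 0; s < n; ++s) {
        double yi = y(s), mi = mu(s);
        if (yi > 0) dev += yi * std::log(yi / mi);
        if (ph > 0) {
          dev -= (yi + 1.0 / ph) *
                 std::log((1.0 + ph * yi) / (1.0 + ph * mi));
        } else {
          dev -= (yi - mi);
        }
      }
      dev *= 2.0;
      if (std::abs(dev - dev_old) < tol * (std::abs(dev) + 0.1)) {
        ok = true;
        dev_old = dev;
        break;
      }
      dev_old = dev;
      if (it == maxit - 1) ok = false;
    }
    beta.row(g) = b.t();
    Mu.row(g) = mu.t();
    converged(g) = ok;
    if (ok) {
      arma::mat cov;
      if (arma::inv_sympd(cov, XtWX)) {
        se.row(g) = arma::sqrt(cov.diag()).t();
      } else {
        converged(g) = false;
      }
    }
  }
  return List::create(_["beta"] = beta, _["se"] = se,
                      _["mu"] = Mu, _["converged"] = converged);
}
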