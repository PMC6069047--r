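// Streaming adaptive-filter core and IIR filtering.
//
// The per-sample ANC loop is the hot path (200 Hz signals, minutes of data,
// a P x P solve per sample), so it lives here; the R-level step functions in
// R/filters.R are the readable reference implementation and the two are
// cross-checked in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Direct-form II transposed IIR filter, a[0] assumed 1 after normalisation.
// [[Rcpp::export(name = ".cpp_iir")]]
NumericVector cpp_iir(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    if (nz > 0) z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}

// Algorithm codes (kept in sync with R/filters.R): 1 APA, 2 APSA, 3 RVSS,
// 4 PROPOSED.  Branch codes: 1 APA, 2 APSA, 3 SKIPPED.
// [[Rcpp::export(name = ".cpp_anc_stream")]]
List cpp_anc_stream(NumericVector d, NumericVector rl, NumericVector rr,
                    int L, int P, int algorithm,
                    double mu, double mu1, double gamma_, double beta_,
                    double alpha_, double delta0, double eps) {
  const int n = d.size();
  const int m = 2 * L;
  arma::vec w(m, arma::fill::zeros);
  arma::mat U(m, P, arma::fill::zeros);
  arma::vec dvec(P, arma::fill::zeros);
  double delta = delta0;

  NumericVector filtered(n), qout(n), stepnorm(n), deltaout(n), eout(n);
  IntegerVector branch(n);

  arma::mat eyeP = arma::eye(P, P);

  for (int i = 0; i < n; ++i) {
    // shift history right, insert newest reference vector / desired sample
    for (int c = P - 1; c > 0; --c) {
      U.col(c) = U.col(c - 1);
      dvec[c] = dvec[c - 1];
    }
    for (int k = 0; k < L; ++k) {
      U(k, 0)     = (i - k >= 0) ? rl[i - k] : 0.0;
      U(L + k, 0) = (i - k >= 0) ? rr[i - k] : 0.0;
    }
    dvec[0] = d[i];

    arma::vec e = dvec - U.t() * w;
    filtered[i] = e[0];
    eout[i] = e[0];

    int br = 1;
    double q = 0.0, snorm = 0.0;

    if (algorithm == 1) {                       // plain APA
      arma::mat G = U.t() * U + eps * eyeP;
      arma::vec upd = mu * (U * arma::solve(G, e, arma::solve_opts::likely_sympd));
      q = arma::norm(upd);
      w += upd;
      snorm = q;
      br = 1;
    } else if (algorithm == 2) {                // plain APSA, fixed step = mu
      arma::vec s = arma::sign(e);
      arma::vec Us = U * s;
      double nn = arma::norm(Us);
      if (nn > 0.0) { w += mu * Us / nn; snorm = mu; br = 2; }
      else          { br = 3; }
    } else if (algorithm == 3) {                // RVSS switch, APA step 1
      arma::mat G = U.t() * U + eps * eyeP;
      arma::vec cand = U * arma::solve(G, e, arma::solve_opts::likely_sympd);
      q = arma::norm(cand);
      if (q < delta) {
        w += cand; snorm = q; br = 1;
      } else {
        arma::vec s = arma::sign(e);
        arma::vec Us = U * s;
        double nn = arma::norm(Us);
        if (nn > 0.0) { w += delta * Us / nn; snorm = delta; br = 2; }
        else          { br = 3; }
      }
      double rn = arma::norm(U.col(0));
      double term = (rn > 0.0) ? std::min(std::abs(e[0]) / rn, delta) : delta;
      delta = alpha_ * delta + (1.0 - alpha_) * term;
    } else {                                    // proposed QRS-preserving switch
      arma::mat G = U.t() * U + eps * eyeP;
      arma::vec upd = mu1 * (U * arma::solve(G, e, arma::solve_opts::likely_sympd));
      q = arma::norm(upd);
      if (q < beta_ * delta) {
        w += upd; snorm = q; br = 1;
        delta = alpha_ * delta + (1.0 - alpha_) * q;
      } else {
        arma::vec s = arma::sign(e);
        arma::vec Us = U * s;
        double nn = arma::norm(Us);
        double step = gamma_ * delta;
        if (nn > 0.0) { w += step * Us / nn; snorm = step; br = 2; }
        else          { br = 3; }
        // delta frozen on the sign-algorithm branch
      }
    }

    branch[i] = br;
    qout[i] = q;
    stepnorm[i] = snorm;
    deltaout[i] = delta;
  }

  return List::create(_["filtered"] = filtered,
                      _["branch"] = branch,
                      _["q"] = qout,
                      _["step_norm"] = stepnorm,
                      _["delta"] = deltaout,
                      _["e"] = eout,
                      _["w_final"] = NumericVector(w.begin(), w.end()));
}
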