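// Inner loop of the Case-2 grid search: for one recording pool and one
// temporal kernel, sweep the candidate ensemble sizes K and, for every
// sampled ensemble, solve the regularized restricted Fisher discriminant,
// project the pool activity on the resulting readout, and accumulate the
// quantities the statistical loss needs:
//   S_e       predicted percept noise variance (Z^2 - sigma_d^2),
//   dbar      cov(rbar_i, u_e) for every pool neuron (the integrated CC
//             prediction up to the kappa factor),
//   Q_in/out  the ensemble-averaged q(u,t) prediction, accumulated as
//             sum_i b_i(u) cov(R_i(t), u_e) over in-/out-of-ensemble
//             neurons (linearity lets all ensembles share one covariance
//             pass against the binned rates),
//   st6       per-ensemble population averages <bbar^2>, <bbar dbar>,
//             <dbar^2> over the ensemble and over its complementary set.
// All covariances use the pooled within-stimulus centring done in R and a
// common denominator `covdenom`.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::export]]
List ensemble_scan_cpp(NumericVector Rc_,      // n x N x B centred binned rates
                       const arma::mat& rbarc, // n x N centred integrated counts
                       const arma::mat& Cbb,   // N x N pooled noise covariance
                       const arma::vec& bbar,  // N integrated tuning
                       const arma::mat& bmat,  // N x B binned tuning b_i(u)
                       List E_list,            // per K: K x nE ensemble indices (1-based)
                       List I_list,            // per K: I x nE complementary sets
                       const arma::vec& lambda,// per K ridge strength
                       double covdenom) {
  IntegerVector dims = Rc_.attr("dim");
  const arma::uword n = dims[0], N = dims[1], B = dims[2];
  arma::cube Rc(Rc_.begin(), n, N, B, false);
  if (rbarc.n_rows != n || rbarc.n_cols != N)
    stop("dimension mismatch between Rc and rbarc");
  const int nK = E_list.size();
  const arma::vec Cdiag = Cbb.diag();
  List out(nK);
  for (int k = 0; k < nK; ++k) {
    arma::umat E = as<arma::umat>(E_list[k]) - 1;  // K x nE
    arma::umat I = as<arma::umat>(I_list[k]) - 1;  // I x nE
    const arma::uword K = E.n_rows, nE = E.n_cols, nI = I.n_rows;
    arma::vec S(nE, arma::fill::zeros);
    arma::mat st6(12, nE, arma::fill::zeros);
    arma::mat dbar_all(N, nE, arma::fill::zeros);
    arma::mat Win(n, N, arma::fill::zeros), Wout(n, N, arma::fill::zeros);
    const double lam = lambda[k];
    const arma::mat rbt = rbarc.t();              // N x n, reused per ensemble
    arma::mat Cr(K, K);
    arma::vec br(K), M, u(n), dall(N);
    for (arma::uword e = 0; e < nE; ++e) {
      const arma::uvec idx = E.col(e);
      const arma::uvec idxI = I.col(e);
      Cr = Cbb.submat(idx, idx);
      Cr.diag() += lam;
      br = bbar.elem(idx);
      bool ok = arma::solve(M, Cr, br, arma::solve_opts::likely_sympd +
                                        arma::solve_opts::no_approx);
      if (!ok) M = arma::pinv(Cr) * br;
      double btM = arma::dot(br, M);
      if (!(btM > 0)) {            // degenerate: no usable information
        S(e) = arma::datum::inf;
        continue;
      }
      S(e) = 1.0 / btM;
      u.zeros();                   // percept noise per trial, unit slope
      for (arma::uword j = 0; j < K; ++j)
        u += rbarc.col(idx(j)) * (M(j) / btM);
      dall = rbt * u / covdenom;   // cov(rbar_i, u_e)
      dbar_all.col(e) = dall;
      for (arma::uword j = 0; j < K; ++j) Win.col(idx(j)) += u;
      for (arma::uword j = 0; j < nI; ++j) Wout.col(idxI(j)) += u;
      // inside the candidate ensemble the integrated CC prediction is
      // exactly proportional to tuning (the restricted-optimality
      // reduction d_in = S_e * bbar, in pre-kappa units), so the V
      // ingredients use that exact form; outside the ensemble only the
      // covariance route exists
      const arma::vec dIn = br / btM, dOut = dall.elem(idxI);
      const arma::vec bOut = bbar.elem(idxI);
      st6(0, e) = arma::mean(arma::square(br));
      st6(1, e) = arma::mean(arma::square(bOut));
      st6(2, e) = arma::mean(br % dIn);
      st6(3, e) = arma::mean(bOut % dOut);
      st6(4, e) = arma::mean(arma::square(dIn));
      st6(5, e) = arma::mean(arma::square(dOut));
      // mean noise-covariance diagonal over each set, for the analytic
      // sampling-noise correction of the squared-indicator predictions
      st6(6, e) = arma::mean(Cdiag.elem(idx));
      st6(7, e) = arma::mean(Cdiag.elem(idxI));
      // finite-neuron sampling noise of the set averages: variance of the
      // per-neuron products (for the qbb^2 term) and covariance of the
      // squared terms (for the <b^2><d^2> product), each over set size
      if (K > 1) {
        arma::vec pin = br % dIn;
        st6(8, e) = arma::var(pin) / K;
        st6(10, e) = arma::as_scalar(
          arma::cov(arma::square(br), arma::square(dIn))) / K;
      }
      if (nI > 1) {
        arma::vec pout = bOut % dOut;
        st6(9, e) = arma::var(pout) / nI;
        st6(11, e) = arma::as_scalar(
          arma::cov(arma::square(bOut), arma::square(dOut))) / nI;
      }
    }
    // Din[i, t] = cov(R_i(t), sum of the u_e of ensembles containing i)
    arma::mat Din(N, B), Dout(N, B);
    for (arma::uword b = 0; b < B; ++b) {
      const double* slice = Rc.slice_memptr(b);
      for (arma::uword i = 0; i < N; ++i) {
        const double* col = slice + i * n;
        double accin = 0.0, accout = 0.0;
        const double* wi = Win.colptr(i);
        const double* wo = Wout.colptr(i);
        for (arma::uword t = 0; t < n; ++t) {
          accin += col[t] * wi[t];
          accout += col[t] * wo[t];
        }
        Din(i, b) = accin / covdenom;
        Dout(i, b) = accout / covdenom;
      }
    }
    arma::mat Qin = bmat.t() * Din / double(nE * K);
    arma::mat Qout = bmat.t() * Dout / double(nE * nI);
    out[k] = List::create(_["S"] = S, _["st6"] = st6,
                          _["dbar"] = dbar_all,
                          _["Qin"] = Qin, _["Qout"] = Qout);
  }
  return out;
}
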