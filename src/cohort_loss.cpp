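// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Matrix exponential (used for the rotation retraction exp of a
// skew-symmetric generator, which is not symmetric, so the symmetric
// eigendecomposition route is not applicable).
// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& X) {
  return arma::expmat(X);
}

static inline double poly_eval(const arma::vec& a, double x) {
  // Horner evaluation of sum_m a_m x^m
  double v = 0.0;
  for (arma::uword m = a.n_elem; m > 0; --m) v = v * x + a(m - 1);
  return v;
}

// Mean squared affine-invariant Riemannian distance between eigenmode
// predictions and observed functional matrices, with eigenvalue clipping
// and an additive penalty for predictions leaving the SPD cone.
//
// family codes: 1 heat kernel, 2 affine diffusion, 3 polynomial,
// 4 rotated spectral, 5 rotated spectral + symmetric constant.
// Qs / lams hold the eigenvectors / eigenvalues of each subject's mapping
// input (Laplacian for families 1-2, structural matrix otherwise);
// Finvhalf holds each subject's F_k^{-1/2}.
// [[Rcpp::export]]
double cpp_cohort_loss(const Rcpp::List& Qs,
                       const Rcpp::List& lams,
                       const Rcpp::List& Finvhalf,
                       int family,
                       const arma::vec& weights,
                       const arma::mat& R,
                       const arma::mat& C,
                       double penalty) {
  const int K = Qs.size();
  double total_d2 = 0.0, total_clip = 0.0;
  const double abs_floor_scale = 1e-10;

  // spectral norm of the constant bounds how far it can move the
  // prediction's eigenvalues; computed once so the per-subject SPD check
  // can usually skip a second eigendecomposition
  double c_norm = 0.0, c_trace = 0.0;
  if (family == 5) {
    arma::vec cev = arma::eig_sym(0.5 * (C + C.t()));
    c_norm = std::max(std::abs(cev.min()), std::abs(cev.max()));
    c_trace = arma::trace(C);
  }

  for (int k = 0; k < K; ++k) {
    arma::mat Q = as<arma::mat>(Qs[k]);
    arma::vec lam = as<arma::vec>(lams[k]);
    arma::mat Fih = as<arma::mat>(Finvhalf[k]);
    const arma::uword M = Q.n_rows;

    arma::vec g(M);
    switch (family) {
      case 1:  // exp(-theta * lambda)
        for (arma::uword i = 0; i < M; ++i) g(i) = std::exp(-weights(0) * lam(i));
        break;
      case 2:  // a * exp(-alpha * lambda) + b
        for (arma::uword i = 0; i < M; ++i)
          g(i) = weights(0) * std::exp(-weights(1) * lam(i)) + weights(2);
        break;
      default: // polynomial weights on the spectrum
        for (arma::uword i = 0; i < M; ++i) g(i) = poly_eval(weights, lam(i));
    }

    arma::mat A;
    if (family == 5) {
      arma::mat RQ = R * Q;
      double fl = abs_floor_scale *
        std::max((arma::sum(g) + c_trace) / (double)M, 1e-8);
      if (g.min() - c_norm > fl) {
        // constant cannot push the spectrum below the floor: no clipping
        arma::mat BQ = Fih * RQ;
        A = BQ * arma::diagmat(g) * BQ.t() + Fih * C * Fih;
      } else {
        arma::mat P = RQ * arma::diagmat(g) * RQ.t() + C;
        P = 0.5 * (P + P.t());
        arma::vec ev; arma::mat V;
        arma::eig_sym(ev, V, P);
        for (arma::uword i = 0; i < M; ++i)
          if (ev(i) < fl) { total_clip += fl - ev(i); ev(i) = fl; }
        arma::mat B = Fih * V;
        A = B * arma::diagmat(ev) * B.t();
      }
    } else {
      // without the constant the prediction's spectrum is g itself
      double fl = abs_floor_scale * std::max(arma::sum(g) / (double)M, 1e-8);
      for (arma::uword i = 0; i < M; ++i)
        if (g(i) < fl) { total_clip += fl - g(i); g(i) = fl; }
      arma::mat B = (family == 4) ? arma::mat(Fih * (R * Q)) : arma::mat(Fih * Q);
      A = B * arma::diagmat(g) * B.t();
    }
    A = 0.5 * (A + A.t());
    arma::vec mu = arma::eig_sym(A);
    double d2 = 0.0;
    for (arma::uword i = 0; i < M; ++i) {
      double m = std::max(mu(i), 1e-300);
      double lg = std::log(m);
      d2 += lg * lg;
    }
    total_d2 += d2;
  }
  return total_d2 / K + penalty * total_clip / K;
}
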