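// Whole-MLP fused kernels: one tape node per MLP application instead of one
// per layer, with Mish activations and their derivatives computed in single
// passes.  gemm goes through Armadillo/BLAS.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
#include "fastexp.h"

// Exact single-exp form: with u = exp(x),
//   tanh(softplus(x)) = (u^2 + 2u) / (u^2 + 2u + 2),  sigmoid(x) = u / (1 + u);
// x is clamped at 300 so u^2 stays finite (tanh(softplus(300)) == 1 anyway).
static inline void mish_inplace(arma::mat& z, arma::mat& d) {
  const arma::uword n = z.n_elem;
  double* pz = z.memptr();
  double* pd = d.memptr();
  // pass 1: exponentials (vectorizable); pass 2: rational algebra
  for (arma::uword i = 0; i < n; ++i) pd[i] = fexp(pz[i]);
  for (arma::uword i = 0; i < n; ++i) {
    double v = pz[i], u = pd[i];
    double w = u * u + 2.0 * u;
    double t = w / (w + 2.0);
    double sig = u / (1.0 + u);
    pz[i] = v * t;
    pd[i] = t + v * (1.0 - t * t) * sig;
  }
}

// Forward through L layers; Mish after every layer except the last.
// Returns the output plus the per-layer inputs and activation derivatives
// needed for the backward pass.
// [[Rcpp::export(name = ".mlp_fwd")]]
List mlp_fwd(const arma::mat& X, List Ws, List bs) {
  int L = Ws.size();
  List acts(L);       // input to layer l (activation of layer l-1)
  List derivs(L - 1); // Mish derivative at hidden layer l
  arma::mat A = X;
  for (int l = 0; l < L; ++l) {
    acts[l] = A;
    arma::mat W = as<arma::mat>(Ws[l]);
    arma::rowvec b = as<arma::rowvec>(bs[l]);
    arma::mat Z = A * W;
    Z.each_row() += b;
    if (l < L - 1) {
      arma::mat D(Z.n_rows, Z.n_cols);
      mish_inplace(Z, D);
      derivs[l] = D;
    }
    A = Z;
  }
  return List::create(_["out"] = A, _["acts"] = acts, _["derivs"] = derivs);
}

// Backward: G is dLoss/dOutput; returns dX and per-layer dW, db.
// [[Rcpp::export(name = ".mlp_bwd")]]
List mlp_bwd(const arma::mat& G0, List Ws, List acts, List derivs) {
  int L = Ws.size();
  List dWs(L), dbs(L);
  arma::mat G = G0;
  for (int l = L - 1; l >= 0; --l) {
    arma::mat A = as<arma::mat>(acts[l]);
    arma::mat W = as<arma::mat>(Ws[l]);
    dWs[l] = A.t() * G;
    dbs[l] = arma::sum(G, 0);
    G = G * W.t();
    if (l > 0) {
      arma::mat D = as<arma::mat>(derivs[l - 1]);
      G %= D;
    }
  }
  return List::create(_["dX"] = G, _["dWs"] = dWs, _["dbs"] = dbs);
}

// Build the per-pair attention input [K[it, ], Q[is, ], u] in one pass.
// it/is are 1-based row indices; u may be a 0-column matrix.
// [[Rcpp::export(name = ".gather_pair_input")]]
arma::mat gather_pair_input(const arma::mat& K, const arma::mat& Q,
                            const arma::uvec& it, const arma::uvec& is,
                            const arma::mat& u) {
  arma::uword P = it.n_elem;
  arma::uword dk = K.n_cols, dq = Q.n_cols, du = u.n_cols;
  arma::mat out(P, dk + dq + du);
  for (arma::uword j = 0; j < dk; ++j) {
    const double* src = K.colptr(j);
    double* dst = out.colptr(j);
    for (arma::uword p = 0; p < P; ++p) dst[p] = src[it[p] - 1];
  }
  for (arma::uword j = 0; j < dq; ++j) {
    const double* src = Q.colptr(j);
    double* dst = out.colptr(dk + j);
    for (arma::uword p = 0; p < P; ++p) dst[p] = src[is[p] - 1];
  }
  for (arma::uword j = 0; j < du; ++j) {
    const double* src = u.colptr(j);
    double* dst = out.colptr(dk + dq + j);
    for (arma::uword p = 0; p < P; ++p) dst[p] = src[p];
  }
  return out;
}

// Scatter-add the gradient of the pair input back onto dK and dQ.
// [[Rcpp::export(name = ".scatter_pair_grad")]]
List scatter_pair_grad(const arma::mat& G, const arma::uvec& it,
                       const arma::uvec& is, int nK, int dk, int dq) {
  arma::uword P = it.n_elem;
  arma::mat dK(nK, dk, arma::fill::zeros);
  arma::mat dQ(nK, dq, arma::fill::zeros);
  for (int j = 0; j < dk; ++j) {
    const double* src = G.colptr(j);
    double* dst = dK.colptr(j);
    for (arma::uword p = 0; p < P; ++p) dst[it[p] - 1] += src[p];
  }
  for (int j = 0; j < dq; ++j) {
    const double* src = G.colptr(dk + j);
    double* dst = dQ.colptr(j);
    for (arma::uword p = 0; p < P; ++p) dst[is[p] - 1] += src[p];
  }
  return List::create(_["dK"] = dK, _["dQ"] = dQ);
}
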