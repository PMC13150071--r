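// Block-diagonal multi-head self-attention kernels. Tokens of a batch are
// stacked as a (B*C) x d matrix (C tokens per sample, sample blocks
// contiguous); attention is computed strictly within each sample block, so
// the cost is linear in B instead of quadratic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void row_softmax_inplace(arma::mat& S) {
  for (arma::uword i = 0; i < S.n_rows; ++i) {
    double m = S.row(i).max();
    S.row(i) = arma::exp(S.row(i) - m);
    S.row(i) /= arma::accu(S.row(i));
  }
}

// Forward: returns the concatenated head outputs O (B*C x d, pre-Wo) and the
// stacked softmax rows P as a (B*C) x C x H cube.
// [[Rcpp::export]]
List block_attn_fwd(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                    int B, int C, int H) {
  const int d = Q.n_cols;
  const int dh = d / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  arma::mat O(B * C, d, arma::fill::zeros);
  arma::cube P(B * C, C, H);
  for (int h = 0; h < H; ++h) {
    const int c0 = h * dh, c1 = (h + 1) * dh - 1;
    for (int b = 0; b < B; ++b) {
      const int r0 = b * C, r1 = (b + 1) * C - 1;
      arma::mat Qb = Q.submat(r0, c0, r1, c1);
      arma::mat Kb = K.submat(r0, c0, r1, c1);
      arma::mat S = Qb * Kb.t() * scale;
      row_softmax_inplace(S);
      P.slice(h).rows(r0, r1) = S;
      O.submat(r0, c0, r1, c1) = S * V.submat(r0, c0, r1, c1);
    }
  }
  return List::create(_["O"] = O, _["P"] = P);
}

// Backward: given the gradient dO w.r.t. the concatenated head outputs,
// returns dQ, dK, dV.
// [[Rcpp::export]]
List block_attn_bwd(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                    const arma::cube& P, const arma::mat& dO,
                    int B, int C, int H) {
  const int d = Q.n_cols;
  const int dh = d / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  arma::mat dQ(B * C, d, arma::fill::zeros);
  arma::mat dK(B * C, d, arma::fill::zeros);
  arma::mat dV(B * C, d, arma::fill::zeros);
  for (int h = 0; h < H; ++h) {
    const int c0 = h * dh, c1 = (h + 1) * dh - 1;
    for (int b = 0; b < B; ++b) {
      const int r0 = b * C, r1 = (b + 1) * C - 1;
      arma::mat A = P.slice(h).rows(r0, r1);
      arma::mat dOh = dO.submat(r0, c0, r1, c1);
      arma::mat Vb = V.submat(r0, c0, r1, c1);
      arma::mat dA = dOh * Vb.t();
      dV.submat(r0, c0, r1, c1) = A.t() * dOh;
      // softmax backward: dS = A % (dA - rowSums(dA % A))
      arma::vec rs = arma::sum(dA % A, 1);
      dA.each_col() -= rs;
      arma::mat dS = A % dA;
      dQ.submat(r0, c0, r1, c1) = dS * K.submat(r0, c0, r1, c1) * scale;
      dK.submat(r0, c0, r1, c1) = dS.t() * Q.submat(r0, c0, r1, c1) * scale;
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
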