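// Full training step (forward + backward) of the pre-LN transformer encoder
// for one minibatch, mirroring the R reference implementation in encoder.R.
// Dropout masks are drawn in R and passed in, so the R RNG stream fully
// determines training. The R forward pass remains the single evaluation
// path; agreement between this kernel's gradients and finite differences of
// the R forward pass is asserted in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct LNCache {
  arma::mat xhat;
  arma::vec inv;
  arma::mat y;
};

LNCache layernorm_fwd(const arma::mat& x, const arma::rowvec& g,
                      const arma::rowvec& b, double eps = 1e-5) {
  LNCache c;
  arma::vec mu = arma::mean(x, 1);
  arma::mat xc = x.each_col() - mu;
  arma::vec v = arma::mean(arma::square(xc), 1);
  c.inv = 1.0 / arma::sqrt(v + eps);
  c.xhat = xc.each_col() % c.inv;
  c.y = c.xhat.each_row() % g;
  c.y.each_row() += b;
  return c;
}

arma::mat layernorm_bwd(const arma::mat& dy, const LNCache& c,
                        const arma::rowvec& g, arma::rowvec& dg,
                        arma::rowvec& db) {
  dg = arma::sum(dy % c.xhat, 0);
  db = arma::sum(dy, 0);
  arma::mat dxhat = dy.each_row() % g;
  arma::vec m1 = arma::mean(dxhat, 1);
  arma::vec m2 = arma::mean(dxhat % c.xhat, 1);
  arma::mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= c.xhat.each_col() % m2;
  dx.each_col() %= c.inv;
  return dx;
}

void row_softmax_inplace(arma::mat& S) {
  for (arma::uword i = 0; i < S.n_rows; ++i) {
    double m = S.row(i).max();
    S.row(i) = arma::exp(S.row(i) - m);
    S.row(i) /= arma::accu(S.row(i));
  }
}

} // namespace

// [[Rcpp::export]]
List encoder_step_cpp(const List& params, const arma::mat& S,
                      const arma::vec& y01, const List& drop_masks,
                      int n_layers, int n_heads, double weight_decay_unused) {
  const int B = S.n_rows;
  const int C = S.n_cols + 1; // classification token first
  const arma::vec w_embed = params["w_embed"];
  const arma::rowvec b_embed =
      arma::conv_to<arma::rowvec>::from(as<arma::vec>(params["b_embed"]));
  const arma::mat pos = params["pos"];
  const int d = w_embed.n_elem;
  const int dh = d / n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);

  // token embedding
  arma::vec s_vec(B * C);
  for (int b = 0; b < B; ++b) {
    s_vec[b * C] = 0.0;
    for (int c = 1; c < C; ++c) s_vec[b * C + c] = S(b, c - 1);
  }
  arma::mat X = s_vec * w_embed.t();
  X.each_row() += b_embed;
  for (int b = 0; b < B; ++b) X.rows(b * C, (b + 1) * C - 1) += pos;

  struct LayerCache {
    arma::mat X_in, N1, Q, K, V, Oc, X1, N2, Hpre, Hrelu;
    arma::cube P;
    LNCache ln1, ln2;
    arma::mat mask1, mask2;
    bool has_mask = false;
  };
  std::vector<LayerCache> caches(n_layers);

  char nm[32];
  for (int l = 1; l <= n_layers; ++l) {
    LayerCache& cl = caches[l - 1];
    cl.X_in = X;
    snprintf(nm, sizeof(nm), "L%d_ln1_g", l);
    arma::rowvec g1 = arma::conv_to<arma::rowvec>::from(as<arma::vec>(params[nm]));
    snprintf(nm, sizeof(nm), "L%d_ln1_b", l);
    arma::rowvec bb1 = arma::conv_to<arma::rowvec>::from(as<arma::vec>(params[nm]));
    cl.ln1 = layernorm_fwd(X, g1, bb1);
    cl.N1 = cl.ln1.y;
    snprintf(nm, sizeof(nm), "L%d_Wq", l); arma::mat Wq = as<arma::mat>(params[nm]);
    snprintf(nm, sizeof(nm), "L%d_Wk", l); arma::mat Wk = as<arma::mat>(params[nm]);
    snprintf(nm, sizeof(nm), "L%d_Wv", l); arma::mat Wv = as<arma::mat>(params[nm]);
    snprintf(nm, sizeof(nm), "L%d_Wo", l); arma::mat Wo = as<arma::mat>(params[nm]);
    cl.Q = cl.N1 * Wq; cl.K = cl.N1 * Wk; cl.V = cl.N1 * Wv;

    arma::mat Oc(B * C, d, arma::fill::zeros);
    cl.P.set_size(B * C, C, n_heads);
    for (int h = 0; h < n_heads; ++h) {
      const int c0 = h * dh, c1 = (h + 1) * dh - 1;
      for (int b = 0; b < B; ++b) {
        const int r0 = b * C, r1 = (b + 1) * C - 1;
        arma::mat Sc = cl.Q.submat(r0, c0, r1, c1) *
                       cl.K.submat(r0, c0, r1, c1).t() * scale;
        row_softmax_inplace(Sc);
        cl.P.slice(h).rows(r0, r1) = Sc;
        Oc.submat(r0, c0, r1, c1) = Sc * cl.V.submat(r0, c0, r1, c1);
      }
    }
    cl.Oc = Oc;
    arma::mat O2 = Oc * Wo;

    List lm = drop_masks[l - 1];
    if (lm.size() == 2) {
      cl.has_mask = true;
      cl.mask1 = as<arma::mat>(lm[0]);
      cl.mask2 = as<arma::mat>(lm[1]);
      O2 %= cl.mask1;
    }
    cl.X1 = X + O2;
    snprintf(nm, sizeof(nm), "L%d_ln2_g", l);
    arma::rowvec g2 = arma::conv_to<arma::rowvec>::from(as<arma::vec>(params[nm]));
    snprintf(nm, sizeof(nm), "L%d_ln2_b", l);
    arma::rowvec bb2 = arma::conv_to<arma::rowvec>::from(as<arma::vec>(params[nm]));
    cl.ln2 = layernorm_fwd(cl.X1, g2, bb2);
    cl.N2 = cl.ln2.y;
    snprintf(nm, sizeof(nm), "L%d_W1", l); arma::mat W1 = as<arma::mat>(params[nm]);
    snprintf(nm, sizeof(nm), "L%d_b1", l);
    arma::rowvec b1f = arma::conv_to<arma::rowvec>::from(as<arma::vec>(params[nm]));
    snprintf(nm, sizeof(nm), "L%d_W2", l); arma::mat W2 = as<arma::mat>(params[nm]);
    snprintf(nm, sizeof(nm), "L%d_b2", l);
    arma::rowvec b2f = arma::conv_to<arma::rowvec>::from(as<arma::vec>(params[nm]));
    cl.Hpre = cl.N2 * W1;
    cl.Hpre.each_row() += b1f;
    cl.Hrelu = cl.Hpre % (cl.Hpre > 0);
    arma::mat F2 = cl.Hrelu * W2;
    F2.each_row() += b2f;
    if (cl.has_mask) F2 %= cl.mask2;
    X = cl.X1 + F2;
  }

  const arma::rowvec lnf_g =
      arma::conv_to<arma::rowvec>::from(as<arma::vec>(params["lnf_g"]));
  const arma::rowvec lnf_b =
      arma::conv_to<arma::rowvec>::from(as<arma::vec>(params["lnf_b"]));
  LNCache lnf = layernorm_fwd(X, lnf_g, lnf_b);
  const arma::vec w_out = params["w_out"];
  const double b_out = as<double>(params["b_out"]);

  arma::uvec cls(B);
  for (int b = 0; b < B; ++b) cls[b] = b * C;
  arma::mat Z = lnf.y.rows(cls);
  arma::vec logit = Z * w_out + b_out;
  arma::vec prob = 1.0 / (1.0 + arma::exp(-logit));
  double loss = 0.0;
  for (int b = 0; b < B; ++b) {
    loss -= y01[b] * std::log(prob[b] + 1e-12) +
            (1 - y01[b]) * std::log(1 - prob[b] + 1e-12);
  }
  loss /= B;

  // ---- backward ----
  List grads;
  arma::vec dlogit = (prob - y01) / B;
  grads["w_out"] = Z.t() * dlogit;
  grads["b_out"] = arma::accu(dlogit);
  arma::mat dlnf_y(B * C, d, arma::fill::zeros);
  dlnf_y.rows(cls) = dlogit * w_out.t();
  arma::rowvec dgf, dbf;
  arma::mat dX = layernorm_bwd(dlnf_y, lnf, lnf_g, dgf, dbf);
  grads["lnf_g"] = dgf.t();
  grads["lnf_b"] = dbf.t();

  for (int l = n_layers; l >= 1; --l) {
    LayerCache& cl = caches[l - 1];
    snprintf(nm, sizeof(nm), "L%d_W1", l); arma::mat W1 = as<arma::mat>(params[nm]);
    snprintf(nm, sizeof(nm), "L%d_W2", l); arma::mat W2 = as<arma::mat>(params[nm]);
    snprintf(nm, sizeof(nm), "L%d_Wq", l); arma::mat Wq = as<arma::mat>(params[nm]);
    snprintf(nm, sizeof(nm), "L%d_Wk", l); arma::mat Wk = as<arma::mat>(params[nm]);
    snprintf(nm, sizeof(nm), "L%d_Wv", l); arma::mat Wv = as<arma::mat>(params[nm]);
    snprintf(nm, sizeof(nm), "L%d_Wo", l); arma::mat Wo = as<arma::mat>(params[nm]);
    snprintf(nm, sizeof(nm), "L%d_ln1_g", l);
    arma::rowvec g1 = arma::conv_to<arma::rowvec>::from(as<arma::vec>(params[nm]));
    snprintf(nm, sizeof(nm), "L%d_ln2_g", l);
    arma::rowvec g2 = arma::conv_to<arma::rowvec>::from(as<arma::vec>(params[nm]));

    // FFN sublayer
    arma::mat dF2 = cl.has_mask ? arma::mat(dX % cl.mask2) : dX;
    snprintf(nm, sizeof(nm), "L%d_W2", l);
    grads[nm] = cl.Hrelu.t() * dF2;
    snprintf(nm, sizeof(nm), "L%d_b2", l);
    grads[nm] = arma::conv_to<arma::vec>::from(arma::sum(dF2, 0));
    arma::mat dHpre = (dF2 * W2.t()) % (cl.Hpre > 0);
    snprintf(nm, sizeof(nm), "L%d_W1", l);
    grads[nm] = cl.N2.t() * dHpre;
    snprintf(nm, sizeof(nm), "L%d_b1", l);
    grads[nm] = arma::conv_to<arma::vec>::from(arma::sum(dHpre, 0));
    arma::rowvec dg2, db2;
    arma::mat dX1 = dX + layernorm_bwd(dHpre * W1.t(), cl.ln2, g2, dg2, db2);
    snprintf(nm, sizeof(nm), "L%d_ln2_g", l);
    grads[nm] = dg2.t();
    snprintf(nm, sizeof(nm), "L%d_ln2_b", l);
    grads[nm] = db2.t();

    // attention sublayer
    arma::mat dO2 = cl.has_mask ? arma::mat(dX1 % cl.mask1) : dX1;
    snprintf(nm, sizeof(nm), "L%d_Wo", l);
    grads[nm] = cl.Oc.t() * dO2;
    arma::mat dOc = dO2 * Wo.t();
    arma::mat dQ(B * C, d, arma::fill::zeros), dK(B * C, d, arma::fill::zeros),
        dV(B * C, d, arma::fill::zeros);
    for (int h = 0; h < n_heads; ++h) {
      const int c0 = h * dh, c1 = (h + 1) * dh - 1;
      for (int b = 0; b < B; ++b) {
        const int r0 = b * C, r1 = (b + 1) * C - 1;
        arma::mat A = cl.P.slice(h).rows(r0, r1);
        arma::mat dOh = dOc.submat(r0, c0, r1, c1);
        arma::mat Vb = cl.V.submat(r0, c0, r1, c1);
        arma::mat dA = dOh * Vb.t();
        dV.submat(r0, c0, r1, c1) = A.t() * dOh;
        arma::vec rs = arma::sum(dA % A, 1);
        dA.each_col() -= rs;
        arma::mat dS = A % dA;
        dQ.submat(r0, c0, r1, c1) = dS * cl.K.submat(r0, c0, r1, c1) * scale;
        dK.submat(r0, c0, r1, c1) = dS.t() * cl.Q.submat(r0, c0, r1, c1) * scale;
      }
    }
    snprintf(nm, sizeof(nm), "L%d_Wq", l); grads[nm] = cl.N1.t() * dQ;
    snprintf(nm, sizeof(nm), "L%d_Wk", l); grads[nm] = cl.N1.t() * dK;
    snprintf(nm, sizeof(nm), "L%d_Wv", l); grads[nm] = cl.N1.t() * dV;
    arma::mat dN1 = dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
    arma::rowvec dg1, db1;
    dX = dX1 + layernorm_bwd(dN1, cl.ln1, g1, dg1, db1);
    snprintf(nm, sizeof(nm), "L%d_ln1_g", l);
    grads[nm] = dg1.t();
    snprintf(nm, sizeof(nm), "L%d_ln1_b", l);
    grads[nm] = db1.t();
  }

  grads["w_embed"] = dX.t() * s_vec;
  grads["b_embed"] = arma::conv_to<arma::vec>::from(arma::sum(dX, 0));
  arma::mat dpos(C, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) dpos += dX.rows(b * C, (b + 1) * C - 1);
  grads["pos"] = dpos;

  return List::create(_["grads"] = grads, _["loss"] = loss,
                      _["prob"] = prob);
}
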