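// Hot numerical kernels for the decoder: temporal convolution, feature-axis
// attention pooling, and per-graph attention. Pure single-threaded dense
// algebra; the R level owns composition, shapes and parameter bookkeeping.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double elu1(double x) { return x > 0 ? x : std::expm1(x); }
static inline double elu_g(double x) { return x > 0 ? 1.0 : std::exp(x); }

// ELU applied in place on a copy (vectorized helper for the R glue)
// [[Rcpp::export]]
arma::mat cpp_elu(const arma::mat& x) {
  mat y = x;
  y.transform([](double v) { return elu1(v); });
  return y;
}

// derivative of ELU from its output: min(y + 1, 1)
// [[Rcpp::export]]
arma::mat cpp_elu_gradout(const arma::mat& y) {
  mat g = y;
  g.transform([](double v) { return v < 0 ? v + 1.0 : 1.0; });
  return g;
}

// 1-D same-padding convolution along time with channel-shared weights.
// M: (R*T) x Din, R rows per time step; W: k x Din x Dout passed as a cube
// (Din x Dout x k, tap-major slices); b: Dout.
// [[Rcpp::export]]
arma::mat cpp_conv1d_forward(const arma::mat& M, const arma::cube& W,
                             const arma::vec& b, const int R) {
  const int n = M.n_rows;
  const int k = W.n_slices;
  const int h = (k - 1) / 2;
  const int Dout = W.n_cols;
  mat out(n, Dout, fill::zeros);
  for (int i = 0; i < k; ++i) {
    const int s = (i - h) * R;
    if (s == 0) {
      out += M * W.slice(i);
    } else if (s > 0) {
      out.rows(0, n - s - 1) += M.rows(s, n - 1) * W.slice(i);
    } else {
      out.rows(-s, n - 1) += M.rows(0, n + s - 1) * W.slice(i);
    }
  }
  out.each_row() += b.t();
  return out;
}

// backward of the convolution; returns dM (optional), dW (cube), db
// [[Rcpp::export]]
Rcpp::List cpp_conv1d_backward(const arma::mat& M, const arma::cube& W,
                               const arma::mat& dOut, const int R,
                               const bool want_dM) {
  const int n = M.n_rows;
  const int k = W.n_slices;
  const int h = (k - 1) / 2;
  cube dW(W.n_rows, W.n_cols, k, fill::zeros);
  mat dM;
  if (want_dM) dM.zeros(n, M.n_cols);
  for (int i = 0; i < k; ++i) {
    const int s = (i - h) * R;
    if (s == 0) {
      dW.slice(i) = M.t() * dOut;
      if (want_dM) dM += dOut * W.slice(i).t();
    } else if (s > 0) {
      dW.slice(i) = M.rows(s, n - 1).t() * dOut.rows(0, n - s - 1);
      if (want_dM)
        dM.rows(s, n - 1) += dOut.rows(0, n - s - 1) * W.slice(i).t();
    } else {
      dW.slice(i) = M.rows(0, n + s - 1).t() * dOut.rows(-s, n - 1);
      if (want_dM)
        dM.rows(0, n + s - 1) += dOut.rows(-s, n - 1) * W.slice(i).t();
    }
  }
  return Rcpp::List::create(Rcpp::Named("dM") = dM,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = sum(dOut, 0).t());
}

// attention pooling forward: softmax over the feature axis of an MLP's
// logits, then the convex combination of the stacked features.
// Xconv: P x F; returns pooled (P), Watt (P x F), A1 (P x H).
// [[Rcpp::export]]
Rcpp::List cpp_att_pool_forward(const arma::mat& Xconv, const arma::mat& W1,
                                const arma::vec& b1, const arma::mat& W2,
                                const arma::vec& b2) {
  mat A1 = Xconv * W1;
  A1.each_row() += b1.t();
  A1.transform([](double v) { return elu1(v); });
  mat ZL = A1 * W2;
  ZL.each_row() += b2.t();
  // row softmax in place, organized column-wise for contiguous access
  const uword Fd = ZL.n_cols;
  vec mx = ZL.col(0);
  for (uword c = 1; c < Fd; ++c) mx = arma::max(mx, ZL.col(c));
  ZL.each_col() -= mx;
  ZL.transform([](double v) { return std::exp(v); });
  vec rs(ZL.n_rows, fill::zeros);
  for (uword c = 0; c < Fd; ++c) rs += ZL.col(c);
  ZL.each_col() /= rs;
  vec pooled(ZL.n_rows, fill::zeros);
  for (uword c = 0; c < Fd; ++c) pooled += ZL.col(c) % Xconv.col(c);
  return Rcpp::List::create(Rcpp::Named("pooled") = pooled,
                            Rcpp::Named("Watt") = ZL,
                            Rcpp::Named("A1") = A1);
}

// backward through the pooling; dPooled: P vector.
// [[Rcpp::export]]
Rcpp::List cpp_att_pool_backward(const arma::vec& dPooled,
                                 const arma::mat& Xconv,
                                 const arma::mat& Watt, const arma::mat& A1,
                                 const arma::vec& pooled,
                                 const arma::mat& W1, const arma::mat& W2) {
  // dz_g = dPooled * w_g * (x_g - pooled); dx_g += w_g * dPooled
  mat dXconv = Watt.each_col() % dPooled;
  mat dZL = dXconv % (Xconv.each_col() - pooled);
  mat dA1 = dZL * W2.t();
  dA1 %= cpp_elu_gradout(A1);
  mat dW2 = A1.t() * dZL;
  mat dW1 = Xconv.t() * dA1;
  dXconv += dA1 * W1.t();
  return Rcpp::List::create(Rcpp::Named("dXconv") = dXconv,
                            Rcpp::Named("dW1") = dW1,
                            Rcpp::Named("db1") = sum(dA1, 0).t(),
                            Rcpp::Named("dW2") = dW2,
                            Rcpp::Named("db2") = sum(dZL, 0).t());
}

// masked attention softmax over each segment's C x C score matrix, then
// neighbor aggregation with an ELU. H: (C*B) x d node-major projections;
// asrc/adst: C*B; LB: C x C log-adjacency bias (-inf off support, 0 diag).
// [[Rcpp::export]]
arma::mat cpp_gat_attention_forward(const arma::mat& H, const arma::vec& asrc,
                                    const arma::vec& adst, const arma::mat& LB,
                                    const int C, const double slope) {
  const int B = H.n_rows / C;
  mat out(H.n_rows, H.n_cols);
  mat S(C, C);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * C;
    for (int v = 0; v < C; ++v) {
      const double av = adst(r0 + v);
      for (int u = 0; u < C; ++u) {
        double e = asrc(r0 + u) + av;
        if (e < 0) e *= slope;
        S(u, v) = e + LB(u, v);
      }
    }
    // row softmax with -inf mask
    for (int u = 0; u < C; ++u) {
      double mx = S.row(u).max();
      double rs = 0;
      for (int v = 0; v < C; ++v) {
        double z = std::exp(S(u, v) - mx);
        S(u, v) = z;
        rs += z;
      }
      S.row(u) /= rs;
    }
    mat pre = S * H.rows(r0, r0 + C - 1);
    pre.transform([](double z) { return elu1(z); });
    out.rows(r0, r0 + C - 1) = pre;
  }
  return out;
}

// backward of the masked attention block: recomputes alpha per segment and
// returns dH, dasrc, dadst for the chain rule above the projections.
// [[Rcpp::export]]
Rcpp::List cpp_gat_attention_backward(const arma::mat& H,
                                      const arma::vec& asrc,
                                      const arma::vec& adst,
                                      const arma::mat& LB, const arma::mat& dOut,
                                      const int C, const double slope) {
  const int B = H.n_rows / C;
  mat dH(H.n_rows, H.n_cols, fill::zeros);
  vec dasrc(H.n_rows, fill::zeros), dadst(H.n_rows, fill::zeros);
  mat S(C, C), preE(C, C);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * C;
    for (int v = 0; v < C; ++v) {
      const double av = adst(r0 + v);
      for (int u = 0; u < C; ++u) {
        double raw = asrc(r0 + u) + av;
        preE(u, v) = raw;
        double e = raw < 0 ? raw * slope : raw;
        S(u, v) = e + LB(u, v);
      }
    }
    for (int u = 0; u < C; ++u) {
      double mx = S.row(u).max();
      double rs = 0;
      for (int v = 0; v < C; ++v) {
        double z = std::exp(S(u, v) - mx);
        S(u, v) = z;
        rs += z;
      }
      S.row(u) /= rs;
    }
    const mat Hb = H.rows(r0, r0 + C - 1);
    mat pre = S * Hb;                       // pre-activation of the ELU
    mat dPre = dOut.rows(r0, r0 + C - 1);
    for (uword i = 0; i < pre.n_elem; ++i) dPre(i) *= elu_g(pre(i));
    mat dAlpha = dPre * Hb.t();             // C x C
    dH.rows(r0, r0 + C - 1) += S.t() * dPre;
    // softmax backward row-wise
    vec rowdot = sum(dAlpha % S, 1);
    mat dS = S % (dAlpha.each_col() - rowdot);
    for (int v = 0; v < C; ++v) {
      for (int u = 0; u < C; ++u) {
        double g = preE(u, v) < 0 ? slope : 1.0;
        double de = dS(u, v) * g;
        dasrc(r0 + u) += de;
        dadst(r0 + v) += de;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dH") = dH,
                            Rcpp::Named("dasrc") = dasrc,
                            Rcpp::Named("dadst") = dadst);
}
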