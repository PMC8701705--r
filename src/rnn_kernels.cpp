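// Batched forward and backward (BPTT) kernels for the LSTM and
// hidden-kernel LSTM (hLSTM) cells.
//
// Layout conventions shared with the R side:
//   X       : cube  B x D x T   (slice t = batch input at step t)
//   active  : mat   B x T       (1 = process step, 0 = skip / carry state;
//                                a step is skipped when its input row is all
//                                zero, the masking-layer contract)
//   Wx      : mat   D x 4U      input kernel, gate column blocks f, i, o, c
//   Wh      : mat   U x 4U      recurrent kernel, same gate order
//   b       : rowvec 4U
//   Hk      : mat   U x 4U      (hLSTM only) per-gate hidden kernels, block g
//                               multiplies ReLU(x_t Wx)_g; no bias
//
// Gate order is fixed as f, i, o, c everywhere (also in serialization).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// Blend rows of `upd` (active rows) with `old` (skipped rows): a is B x 1.
static inline mat blend(const mat& upd, const mat& old, const vec& a) {
  return upd.each_col() % a + old.each_col() % (1.0 - a);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List cpp_lstm_forward(const arma::cube& X, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::rowvec& b,
                            const arma::mat& active) {
  const uword B = X.n_rows, T = X.n_slices;
  const uword U = Wh.n_rows;
  cube H(B, U, T), C(B, U, T), G(B, 4 * U, T);
  mat h(B, U, fill::zeros), c(B, U, fill::zeros);

  for (uword t = 0; t < T; ++t) {
    mat Z = X.slice(t) * Wx + h * Wh;
    Z.each_row() += b;
    mat f = sigmoid(Z.cols(0, U - 1));
    mat i = sigmoid(Z.cols(U, 2 * U - 1));
    mat o = sigmoid(Z.cols(2 * U, 3 * U - 1));
    mat g = tanh(Z.cols(3 * U, 4 * U - 1));
    mat c_new = f % c + i % g;
    mat h_new = o % tanh(c_new);
    vec a = active.col(t);
    c = blend(c_new, c, a);
    h = blend(h_new, h, a);
    G.slice(t) = join_rows(f, i, o, g);
    C.slice(t) = c;
    H.slice(t) = h;
  }
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("C") = C,
                            Rcpp::Named("G") = G);
}

// dH carries the gradient w.r.t. the emitted hidden state at every step
// (zero slices where the output is unused); returns parameter gradients and
// the gradient w.r.t. the input sequence for stacked layers.
// [[Rcpp::export(rng = false)]]
Rcpp::List cpp_lstm_backward(const arma::cube& X, const arma::mat& Wx,
                             const arma::mat& Wh, const arma::cube& H,
                             const arma::cube& C, const arma::cube& G,
                             const arma::mat& active, const arma::cube& dH) {
  const uword B = X.n_rows, D = X.n_cols, T = X.n_slices;
  const uword U = Wh.n_rows;
  mat dWx(D, 4 * U, fill::zeros), dWh(U, 4 * U, fill::zeros);
  rowvec db(4 * U, fill::zeros);
  cube dX(B, D, T, fill::zeros);
  mat dh(B, U, fill::zeros), dc(B, U, fill::zeros);

  for (uword t = T; t-- > 0;) {
    vec a = active.col(t);
    mat dh_tot = dH.slice(t) + dh;
    mat f = G.slice(t).cols(0, U - 1);
    mat i = G.slice(t).cols(U, 2 * U - 1);
    mat o = G.slice(t).cols(2 * U, 3 * U - 1);
    mat g = G.slice(t).cols(3 * U, 4 * U - 1);
    mat tc = tanh(C.slice(t));
    mat c_prev = (t > 0) ? mat(C.slice(t - 1)) : mat(B, U, fill::zeros);
    mat h_prev = (t > 0) ? mat(H.slice(t - 1)) : mat(B, U, fill::zeros);

    mat dct = dc + dh_tot % o % (1.0 - tc % tc);
    mat dZ = join_rows((dct % c_prev) % f % (1.0 - f),
                       (dct % g) % i % (1.0 - i),
                       (dh_tot % tc) % o % (1.0 - o),
                       (dct % i) % (1.0 - g % g));
    dZ.each_col() %= a;  // no gate gradient at skipped steps

    dWx += X.slice(t).t() * dZ;
    dWh += h_prev.t() * dZ;
    db += sum(dZ, 0);
    dX.slice(t) = dZ * Wx.t();
    dh = blend(dZ * Wh.t(), dh_tot, a);  // skipped rows pass dh through
    dc = blend(dct % f, dc, a);
  }
  return Rcpp::List::create(Rcpp::Named("dWx") = dWx, Rcpp::Named("dWh") = dWh,
                            Rcpp::Named("db") = db, Rcpp::Named("dX") = dX);
}

// hLSTM: per-gate pre-activation z_g = h_prev W_h,g + ReLU(x_t W_x,g) H_g + b_g.
// [[Rcpp::export(rng = false)]]
Rcpp::List cpp_hlstm_forward(const arma::cube& X, const arma::mat& Wx,
                             const arma::mat& Wh, const arma::mat& Hk,
                             const arma::rowvec& b, const arma::mat& active) {
  const uword B = X.n_rows, T = X.n_slices;
  const uword U = Wh.n_rows;
  cube H(B, U, T), C(B, U, T), G(B, 4 * U, T), R(B, 4 * U, T);
  mat h(B, U, fill::zeros), c(B, U, fill::zeros);

  for (uword t = 0; t < T; ++t) {
    mat r = clamp(X.slice(t) * Wx, 0.0, datum::inf);  // ReLU of input kernel
    mat Z = h * Wh;
    for (uword gi = 0; gi < 4; ++gi) {
      uword lo = gi * U, hi = (gi + 1) * U - 1;
      Z.cols(lo, hi) += r.cols(lo, hi) * Hk.cols(lo, hi);
    }
    Z.each_row() += b;
    mat f = sigmoid(Z.cols(0, U - 1));
    mat i = sigmoid(Z.cols(U, 2 * U - 1));
    mat o = sigmoid(Z.cols(2 * U, 3 * U - 1));
    mat g = tanh(Z.cols(3 * U, 4 * U - 1));
    mat c_new = f % c + i % g;
    mat h_new = o % tanh(c_new);
    vec a = active.col(t);
    c = blend(c_new, c, a);
    h = blend(h_new, h, a);
    G.slice(t) = join_rows(f, i, o, g);
    R.slice(t) = r;
    C.slice(t) = c;
    H.slice(t) = h;
  }
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("C") = C,
                            Rcpp::Named("G") = G, Rcpp::Named("R") = R);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List cpp_hlstm_backward(const arma::cube& X, const arma::mat& Wx,
                              const arma::mat& Wh, const arma::mat& Hk,
                              const arma::cube& H, const arma::cube& C,
                              const arma::cube& G, const arma::cube& R,
                              const arma::mat& active, const arma::cube& dH) {
  const uword B = X.n_rows, D = X.n_cols, T = X.n_slices;
  const uword U = Wh.n_rows;
  mat dWx(D, 4 * U, fill::zeros), dWh(U, 4 * U, fill::zeros);
  mat dHk(U, 4 * U, fill::zeros);
  rowvec db(4 * U, fill::zeros);
  cube dX(B, D, T, fill::zeros);
  mat dh(B, U, fill::zeros), dc(B, U, fill::zeros);

  for (uword t = T; t-- > 0;) {
    vec a = active.col(t);
    mat dh_tot = dH.slice(t) + dh;
    mat f = G.slice(t).cols(0, U - 1);
    mat i = G.slice(t).cols(U, 2 * U - 1);
    mat o = G.slice(t).cols(2 * U, 3 * U - 1);
    mat g = G.slice(t).cols(3 * U, 4 * U - 1);
    mat tc = tanh(C.slice(t));
    mat c_prev = (t > 0) ? mat(C.slice(t - 1)) : mat(B, U, fill::zeros);
    mat h_prev = (t > 0) ? mat(H.slice(t - 1)) : mat(B, U, fill::zeros);

    mat dct = dc + dh_tot % o % (1.0 - tc % tc);
    mat dZ = join_rows((dct % c_prev) % f % (1.0 - f),
                       (dct % g) % i % (1.0 - i),
                       (dh_tot % tc) % o % (1.0 - o),
                       (dct % i) % (1.0 - g % g));
    dZ.each_col() %= a;

    const mat& r = R.slice(t);
    mat dA(B, 4 * U);
    for (uword gi = 0; gi < 4; ++gi) {
      uword lo = gi * U, hi = (gi + 1) * U - 1;
      dHk.cols(lo, hi) += r.cols(lo, hi).t() * dZ.cols(lo, hi);
      dA.cols(lo, hi) = dZ.cols(lo, hi) * Hk.cols(lo, hi).t();
    }
    dA %= conv_to<mat>::from(r > 0.0);  // through the ReLU

    dWx += X.slice(t).t() * dA;
    dWh += h_prev.t() * dZ;
    db += sum(dZ, 0);
    dX.slice(t) = dA * Wx.t();
    dh = blend(dZ * Wh.t(), dh_tot, a);
    dc = blend(dct % f, dc, a);
  }
  return Rcpp::List::create(Rcpp::Named("dWx") = dWx, Rcpp::Named("dWh") = dWh,
                            Rcpp::Named("dHk") = dHk, Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}
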