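#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Causal multi-head attention forward.
// Q,K,V: (B*T) x d, rows grouped in blocks of T per sequence.
// Returns O ((B*T) x d) and attention probabilities cube (T x T x B*H).
// [[Rcpp::export]]
Rcpp::List attn_fwd_cpp(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                        int T, int H) {
  const int d = Q.n_cols, B = Q.n_rows / T, dh = d / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat O(Q.n_rows, d, fill::zeros);
  cube P(T, T, (size_t)B * H, fill::zeros);
  for (int b = 0; b < B; ++b) {
    int r0 = b * T;
    for (int h = 0; h < H; ++h) {
      int c0 = h * dh;
      mat Qh = Q.submat(r0, c0, r0 + T - 1, c0 + dh - 1);
      mat Kh = K.submat(r0, c0, r0 + T - 1, c0 + dh - 1);
      mat Vh = V.submat(r0, c0, r0 + T - 1, c0 + dh - 1);
      mat S = Qh * Kh.t() * scale;
      mat& Pm = P.slice((size_t)b * H + h);
      for (int i = 0; i < T; ++i) {
        rowvec s = S.row(i).cols(0, i);
        s -= s.max();
        rowvec e = exp(s);
        Pm.row(i).cols(0, i) = e / accu(e);
      }
      O.submat(r0, c0, r0 + T - 1, c0 + dh - 1) = Pm * Vh;
    }
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("P") = P);
}

// [[Rcpp::export]]
Rcpp::List attn_bwd_cpp(const arma::mat& dO, const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                        const arma::cube& P, int T, int H) {
  const int d = Q.n_cols, B = Q.n_rows / T, dh = d / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat dQ(size(Q), fill::zeros), dK(size(K), fill::zeros), dV(size(V), fill::zeros);
  for (int b = 0; b < B; ++b) {
    int r0 = b * T;
    for (int h = 0; h < H; ++h) {
      int c0 = h * dh;
      const mat& Pm = P.slice((size_t)b * H + h);
      mat Qh = Q.submat(r0, c0, r0 + T - 1, c0 + dh - 1);
      mat Kh = K.submat(r0, c0, r0 + T - 1, c0 + dh - 1);
      mat Vh = V.submat(r0, c0, r0 + T - 1, c0 + dh - 1);
      mat dOh = dO.submat(r0, c0, r0 + T - 1, c0 + dh - 1);
      mat dP = dOh * Vh.t();
      mat dS = Pm % (dP.each_col() - sum(dP % Pm, 1));
      dQ.submat(r0, c0, r0 + T - 1, c0 + dh - 1) = dS * Kh * scale;
      dK.submat(r0, c0, r0 + T - 1, c0 + dh - 1) = dS.t() * Qh * scale;
      dV.submat(r0, c0, r0 + T - 1, c0 + dh - 1) = Pm.t() * dOh;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ, Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}
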