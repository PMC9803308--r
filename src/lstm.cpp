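// Sequential LSTM forward / backward passes. These are the only
// time-critical loops in the package (370 time steps per direction per
// batch); everything around them stays in R. Layouts match the R reference
// implementations: state cubes are (batch, hidden, time).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Xp: (B, 4H, T) cube of input projections (Wx x_t + b already applied).
// dir: +1 forward, -1 backward traversal.
// [[Rcpp::export(name = ".lstm_forward_cpp")]]
Rcpp::List lstm_forward_cpp(const arma::cube& Xp, const arma::mat& Wh,
                            int dir) {
  const uword B = Xp.n_rows, H4 = Xp.n_cols, T = Xp.n_slices;
  const uword H = H4 / 4;
  cube Gates(B, H4, T), Cs(B, H, T), TC(B, H, T), Hs(B, H, T);
  mat h(B, H, fill::zeros), cs(B, H, fill::zeros);
  for (uword k = 0; k < T; ++k) {
    uword t = (dir > 0) ? k : (T - 1 - k);
    mat G = Xp.slice(t) + h * Wh;
    mat A(B, H4);
    A.cols(0, H - 1) = sigm(G.cols(0, H - 1));
    A.cols(H, 2 * H - 1) = sigm(G.cols(H, 2 * H - 1));
    A.cols(2 * H, 3 * H - 1) = tanh(G.cols(2 * H, 3 * H - 1));
    A.cols(3 * H, 4 * H - 1) = sigm(G.cols(3 * H, 4 * H - 1));
    cs = A.cols(H, 2 * H - 1) % cs +
         A.cols(0, H - 1) % A.cols(2 * H, 3 * H - 1);
    mat tc = tanh(cs);
    h = A.cols(3 * H, 4 * H - 1) % tc;
    Gates.slice(t) = A;
    Cs.slice(t) = cs;
    TC.slice(t) = tc;
    Hs.slice(t) = h;
  }
  return Rcpp::List::create(Rcpp::Named("Gates") = Gates,
                            Rcpp::Named("Cs") = Cs,
                            Rcpp::Named("TC") = TC,
                            Rcpp::Named("Hs") = Hs);
}

// dH: (B, H, T) gradient into the hidden states.
// Returns dXp (B, 4H, T) plus the summed recurrent-weight gradient term
// computed outside in R (dWh needs the shifted hidden states; cheaper to
// return dXp and let R do two big crossprods).
// [[Rcpp::export(name = ".lstm_backward_cpp")]]
arma::cube lstm_backward_cpp(const arma::cube& Gates, const arma::cube& Cs,
                             const arma::cube& TC, const arma::mat& Wh,
                             const arma::cube& dH, int dir) {
  const uword B = Gates.n_rows, H4 = Gates.n_cols, T = Gates.n_slices;
  const uword H = H4 / 4;
  cube dXp(B, H4, T);
  mat dh_rec(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  mat tWh = Wh.t();
  for (uword k = T; k-- > 0;) {
    // traversal order was ord = dir>0 ? 0..T-1 : T-1..0; iterate reverse
    uword t = (dir > 0) ? k : (T - 1 - k);
    uword t_prev_valid = (k > 0);
    mat c_prev(B, H, fill::zeros);
    if (t_prev_valid) {
      uword t_prev = (dir > 0) ? (k - 1) : (T - k);
      c_prev = Cs.slice(t_prev);
    }
    const mat& A = Gates.slice(t);
    mat ig = A.cols(0, H - 1), fg = A.cols(H, 2 * H - 1);
    mat gg = A.cols(2 * H, 3 * H - 1), og = A.cols(3 * H, 4 * H - 1);
    mat tc = TC.slice(t);
    mat dh = dH.slice(t) + dh_rec;
    mat dc = dc_next + dh % og % (1.0 - tc % tc);
    mat dG(B, H4);
    dG.cols(0, H - 1) = (dc % gg) % ig % (1.0 - ig);
    dG.cols(H, 2 * H - 1) = (dc % c_prev) % fg % (1.0 - fg);
    dG.cols(2 * H, 3 * H - 1) = (dc % ig) % (1.0 - gg % gg);
    dG.cols(3 * H, 4 * H - 1) = (dh % tc) % og % (1.0 - og);
    dc_next = dc % fg;
    dXp.slice(t) = dG;
    dh_rec = dG * tWh;
  }
  return dXp;
}
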