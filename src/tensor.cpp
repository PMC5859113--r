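#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Per-voxel temporal tensor: assemble the 4x4 symmetric matrix with diagonal
// i_t^2 and off-diagonal (i_a - i_b)^2, eigendecompose, and return the sum of
// the three largest eigenvalues. X is n_voxels x 4 (pre, post1..3).
// [[Rcpp::export]]
Rcpp::NumericVector tensor_trace_core(const arma::mat& X) {
  const arma::uword n = X.n_rows;
  const arma::uword k = X.n_cols;
  Rcpp::NumericVector out(n);
  arma::mat A(k, k);
  arma::vec ev;
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword a = 0; a < k; ++a) {
      A(a, a) = X(i, a) * X(i, a);
      for (arma::uword b = a + 1; b < k; ++b) {
        const double d = X(i, a) - X(i, b);
        A(a, b) = d * d;
        A(b, a) = d * d;
      }
    }
    arma::eig_sym(ev, A);  // ascending
    out[i] = arma::accu(ev.tail(3));
  }
  return out;
}
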