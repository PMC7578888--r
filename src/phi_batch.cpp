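#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Batch first-passage solve for the donor->acceptor absorption probability.
//
// For one replicate the excitation starting on donor i is absorbed by the
// acceptor with probability h_i satisfying
//   (k_d + k_da_i + sum_j K_ij) h_i - sum_j K_ij h_j = k_da_i,
// i.e. A h = k_da with A = diag(k_d + k_da + rowSums(K)) - K.
// A is a strictly diagonally dominant M-matrix whenever k_d > 0, so the
// solve is well posed; rate capping upstream keeps it well conditioned.
//
// k_da : n x m matrix, column r = donor->acceptor rates of replicate r
// k_dd : npair x m matrix, row p = rate of unordered donor pair p
// pairs: npair x 2 integer matrix of 1-based donor indices
// k_d  : intrinsic donor decay rate (same units as the transfer rates)
//
// Returns an n x m matrix of per-donor absorption probabilities.
// [[Rcpp::export]]
arma::mat phi_batch_cpp(const arma::mat& k_da, const arma::mat& k_dd,
                        const arma::imat& pairs, double k_d) {
  const arma::uword n = k_da.n_rows, m = k_da.n_cols, np = pairs.n_rows;
  if (np > 0 && k_dd.n_rows != np)
    Rcpp::stop("k_dd must have one row per donor pair");
  if (np > 0 && k_dd.n_cols != m)
    Rcpp::stop("k_dd and k_da must have the same number of replicates");
  arma::mat phi(n, m);
  arma::mat A(n, n);
  for (arma::uword r = 0; r < m; ++r) {
    A.zeros();
    for (arma::uword p = 0; p < np; ++p) {
      const arma::uword i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
      const double k = k_dd(p, r);
      A(i, j) -= k;
      A(j, i) -= k;
      A(i, i) += k;
      A(j, j) += k;
    }
    for (arma::uword i = 0; i < n; ++i) A(i, i) += k_d + k_da(i, r);
    phi.col(r) = arma::solve(A, k_da.col(r),
                             arma::solve_opts::fast + arma::solve_opts::no_approx);
  }
  return phi;
}
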