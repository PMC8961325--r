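#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Exact propagation of the linear system dy/dt = A y + b(t), where the
// forcing b(t) is piecewise linear between knots and clamps to the nearest
// knot value outside the knot range. Because the model class is linear with
// piecewise-linear forcing, each sub-interval is solved in closed form via
// the augmented matrix exponential
//   M = [ A  b0  b1 ]
//       [ 0   0   0  ]
//       [ 0   1   0  ]
// so exp(M h) applied to (y, 1, 0) yields y(t0 + h) exactly (to the accuracy
// of expmat), with b(t0 + s) = b0 + b1 s on the sub-interval.

static arma::vec step_exact(const arma::mat& A, const arma::vec& y,
                            const arma::vec& b0, const arma::vec& b1,
                            double h) {
  const arma::uword n = y.n_elem;
  arma::mat M(n + 2, n + 2, arma::fill::zeros);
  M.submat(0, 0, n - 1, n - 1) = A;
  for (arma::uword i = 0; i < n; ++i) {
    M(i, n) = b0(i);
    M(i, n + 1) = b1(i);
  }
  // augmented clock: w' = 0 (w = 1), z' = w (z = elapsed time), so that
  // y' = A y + b0 w + b1 z reproduces the linear-in-time forcing
  M(n + 1, n) = 1.0;
  arma::mat E = arma::expmat(M * h);
  arma::vec aug(n + 2, arma::fill::zeros);
  aug.head(n) = y;
  aug(n) = 1.0;
  arma::vec out = E * aug;
  return out.head(n);
}

// Local forcing segment at time t: value b0 (at t) and slope b1.
static void forcing_at(const arma::vec& knot_t, const arma::mat& knot_b,
                       double t, arma::vec& b0, arma::vec& b1) {
  const arma::uword K = knot_t.n_elem;
  if (t < knot_t(0)) {
    b0 = knot_b.col(0);
    b1.zeros();
    return;
  }
  if (t >= knot_t(K - 1)) {
    b0 = knot_b.col(K - 1);
    b1.zeros();
    return;
  }
  arma::uword j = 0;
  while (j + 2 < K && knot_t(j + 1) <= t) ++j;
  // knot_t(j) <= t < knot_t(j+1)
  double dt = knot_t(j + 1) - knot_t(j);
  b1 = (knot_b.col(j + 1) - knot_b.col(j)) / dt;
  b0 = knot_b.col(j) + b1 * (t - knot_t(j));
}

// [[Rcpp::export]]
arma::mat ode_propagate_cpp(const arma::mat& A, const arma::vec& y0,
                            const arma::vec& knot_t, const arma::mat& knot_b,
                            const arma::vec& out_t) {
  const arma::uword n = y0.n_elem;
  const arma::uword K = knot_t.n_elem;
  const arma::uword m = out_t.n_elem;
  if (A.n_rows != n || A.n_cols != n)
    Rcpp::stop("A must be square and conform to the state dimension");
  if (knot_b.n_rows != n || knot_b.n_cols != K)
    Rcpp::stop("knot_b must be n_state x n_knots");
  for (arma::uword k = 1; k < K; ++k)
    if (knot_t(k) <= knot_t(k - 1))
      Rcpp::stop("knot times must be strictly increasing");
  for (arma::uword k = 1; k < m; ++k)
    if (out_t(k) <= out_t(k - 1))
      Rcpp::stop("output times must be strictly increasing");

  arma::mat out(n, m);
  arma::vec y = y0;
  out.col(0) = y;
  double t_cur = out_t(0);
  arma::vec b0(n), b1(n);

  for (arma::uword k = 1; k < m; ++k) {
    double t_end = out_t(k);
    while (t_cur < t_end) {
      // next event: the nearest interior knot or the output time
      double t_next = t_end;
      for (arma::uword j = 0; j < K; ++j) {
        if (knot_t(j) > t_cur && knot_t(j) < t_next) t_next = knot_t(j);
      }
      forcing_at(knot_t, knot_b, t_cur, b0, b1);
      y = step_exact(A, y, b0, b1, t_next - t_cur);
      t_cur = t_next;
    }
    out.col(k) = y;
  }
  return out;
}
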