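#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Fast path of the joint weighted least-squares cost. The R-level cost()
// is the readable reference implementation; this one is used inside the
// optimizer and sampler loops. Both are tested against each other.

arma::mat ode_propagate_cpp(const arma::mat& A, const arma::vec& y0,
                            const arma::vec& knot_t, const arma::mat& knot_b,
                            const arma::vec& out_t);

static arma::mat system_matrix_cpp(const arma::vec& r) {
  // r: k_GLY, k_LDHf, k_LDHb, k_ALTf, k_ALTb, k_TCA, k_Pro,
  //    d_pyr, d_lac, d_ala, d_cit
  arma::mat A(4, 4, arma::fill::zeros);
  A(0, 0) = -(r(1) + r(3) + r(5) + r(7));
  A(0, 1) = r(2);
  A(0, 2) = r(4);
  A(1, 0) = r(1);
  A(1, 1) = -(r(2) + r(8));
  A(2, 0) = r(3);
  A(2, 2) = -(r(4) + r(9));
  A(3, 0) = r(5);
  A(3, 3) = -r(10);
  return A;
}

// theta (length 21, log10): 10 reference rates (k_Pro omitted), 10 ratios,
// 1 k_Pro/k_GLY ratio of the second intervention.
static void theta_to_rates_cpp(const arma::vec& theta, arma::vec& ref,
                               arma::vec& alt) {
  // free order: k_GLY,k_LDHf,k_LDHb,k_ALTf,k_ALTb,k_TCA,d_pyr,d_lac,d_ala,d_cit
  arma::vec f(10), a(10);
  for (int i = 0; i < 10; ++i) {
    f(i) = std::pow(10.0, theta(i));
    a(i) = f(i) * std::pow(10.0, theta(10 + i));
  }
  ref.set_size(11);
  alt.set_size(11);
  // insert k_Pro at position 6
  for (int i = 0; i < 6; ++i) { ref(i) = f(i); alt(i) = a(i); }
  ref(6) = 0.0;
  alt(6) = a(0) * std::pow(10.0, theta(20));
  for (int i = 6; i < 10; ++i) { ref(i + 1) = f(i); alt(i + 1) = a(i); }
}

// [[Rcpp::export]]
double joint_cost_cpp(const arma::vec& theta, const Rcpp::List& packed) {
  arma::vec ref, alt;
  theta_to_rates_cpp(theta, ref, alt);
  double total = 0.0;
  for (int j = 0; j < packed.size(); ++j) {
    Rcpp::List d = packed[j];
    const arma::vec rates = (j == 0) ? ref : alt;
    arma::vec knot_t = d["knot_t"];
    arma::vec glc = d["glc"];
    arma::vec pro = d["pro"];
    arma::vec sim_t = d["sim_times"];
    arma::mat y = d["y"];
    arma::mat sd = d["sd"];
    arma::vec s = d["s"];
    arma::vec init = d["init"];
    bool prepend = Rcpp::as<bool>(d["prepend"]);
    arma::mat knot_b(4, knot_t.n_elem, arma::fill::zeros);
    knot_b.row(0) = rates(0) * glc.t();
    knot_b.row(2) = rates(6) * pro.t();
    arma::mat A = system_matrix_cpp(rates);
    arma::mat st;
    try {
      st = ode_propagate_cpp(A, init, knot_t, knot_b, sim_t);
    } catch (...) {
      return R_PosInf;
    }
    // st: 4 x n_times; drop the prepended start column if present
    arma::uword off = prepend ? 1 : 0;
    arma::uword n = sim_t.n_elem - off;
    for (arma::uword k = 0; k < n; ++k) {
      for (arma::uword i = 0; i < 4; ++i) {
        double res = (y(k, i) - st(i, k + off) * s(k)) / sd(k, i);
        total += res * res;
      }
    }
    if (!std::isfinite(total)) return R_PosInf;
  }
  return total;
}

// Scaled residual vector (y - yhat)/sd, concatenated over interventions,
// time points and species; used by the Levenberg-Marquardt polish.
// [[Rcpp::export]]
arma::vec joint_resid_cpp(const arma::vec& theta, const Rcpp::List& packed) {
  arma::vec ref, alt;
  theta_to_rates_cpp(theta, ref, alt);
  std::vector<double> out;
  for (int j = 0; j < packed.size(); ++j) {
    Rcpp::List d = packed[j];
    const arma::vec rates = (j == 0) ? ref : alt;
    arma::vec knot_t = d["knot_t"];
    arma::vec glc = d["glc"];
    arma::vec pro = d["pro"];
    arma::vec sim_t = d["sim_times"];
    arma::mat y = d["y"];
    arma::mat sd = d["sd"];
    arma::vec s = d["s"];
    arma::vec init = d["init"];
    bool prepend = Rcpp::as<bool>(d["prepend"]);
    arma::mat knot_b(4, knot_t.n_elem, arma::fill::zeros);
    knot_b.row(0) = rates(0) * glc.t();
    knot_b.row(2) = rates(6) * pro.t();
    arma::mat A = system_matrix_cpp(rates);
    arma::mat st = ode_propagate_cpp(A, init, knot_t, knot_b, sim_t);
    arma::uword off = prepend ? 1 : 0;
    arma::uword n = sim_t.n_elem - off;
    for (arma::uword k = 0; k < n; ++k)
      for (arma::uword i = 0; i < 4; ++i)
        out.push_back((y(k, i) - st(i, k + off) * s(k)) / sd(k, i));
  }
  return arma::vec(out);
}
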