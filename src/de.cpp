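#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Differential evolution (best/1/bin with reflection at the box) driving the
// compiled joint cost. Uses R's RNG so runs are reproducible under set.seed.

double joint_cost_cpp(const arma::vec& theta, const Rcpp::List& packed);

static int rand_index(int n) {
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// [[Rcpp::export]]
Rcpp::List de_cost_optimize_cpp(const Rcpp::List& packed,
                                const arma::vec& lower, const arma::vec& upper,
                                int popsize, int maxiter, double F, double CR,
                                double reltol, int patience,
                                const arma::mat& init) {
  const int d = lower.n_elem;
  arma::mat pop(popsize, d);
  for (int i = 0; i < popsize; ++i)
    for (int j = 0; j < d; ++j)
      pop(i, j) = lower(j) + unif_rand() * (upper(j) - lower(j));
  int n_seed = std::min((int)init.n_rows, popsize);
  for (int i = 0; i < n_seed; ++i)
    for (int j = 0; j < d; ++j)
      pop(i, j) = std::min(upper(j), std::max(lower(j), init(i, j)));

  arma::vec vals(popsize);
  long evals = 0;
  for (int i = 0; i < popsize; ++i) {
    vals(i) = joint_cost_cpp(pop.row(i).t(), packed);
    ++evals;
  }
  arma::uword best_i = vals.index_min();
  double best_val = vals(best_i);
  int stall = 0, iter = 0;
  arma::vec trial(d);
  while (iter < maxiter) {
    ++iter;
    double prev_best = best_val;
    for (int i = 0; i < popsize; ++i) {
      int a = rand_index(popsize - 1); if (a >= i) ++a;
      int b;
      do { b = rand_index(popsize - 1); if (b >= i) ++b; } while (b == a);
      int jrand = rand_index(d);
      for (int j = 0; j < d; ++j) {
        if (j == jrand || unif_rand() < CR) {
          double v = pop(best_i, j) + F * (pop(a, j) - pop(b, j));
          if (v > upper(j)) v = std::max(lower(j), 2 * upper(j) - v);
          if (v < lower(j)) v = std::min(upper(j), 2 * lower(j) - v);
          trial(j) = v;
        } else {
          trial(j) = pop(i, j);
        }
      }
      double tv = joint_cost_cpp(trial, packed);
      ++evals;
      if (tv <= vals(i)) {
        pop.row(i) = trial.t();
        vals(i) = tv;
        if (tv < best_val) { best_val = tv; best_i = i; }
      }
    }
    bool improved = (prev_best - best_val) > reltol * (std::abs(prev_best) + reltol);
    stall = improved ? 0 : stall + 1;
    if (stall >= patience) break;
  }
  return Rcpp::List::create(
    Rcpp::Named("par") = pop.row(best_i).t(),
    Rcpp::Named("value") = best_val,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("evaluations") = (double)evals);
}
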