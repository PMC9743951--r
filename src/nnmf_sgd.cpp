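#include <Rcpp.h>
using namespace Rcpp;

// Stochastic-gradient training loop for biased non-negative matrix
// factorization. One iteration = one pass over all observed ratings in a
// freshly shuffled order (R's RNG, so set.seed() upstream controls it).
// For each cell: e = r - (mu + b_u + b_i + q_i'p_u), then the bias and
// factor updates are applied sequentially and the touched factor vectors
// are projected onto the non-negative orthant.
//
// Factor matrices are handled as f x n_users (Wt) and f x n_items (H) so
// each cell touches two contiguous columns.
// [[Rcpp::export]]
List nnmf_sgd_core(NumericVector r, IntegerVector ui, IntegerVector ii,
                   NumericMatrix Wt0, NumericMatrix H0,
                   NumericVector bu0, NumericVector bi0,
                   double mu, double gamma,
                   double lam_bu, double lam_bi, double lam_pu, double lam_qi,
                   double tol, int max_iter, bool check_nonneg) {
  int n_obs = r.size();
  int f = Wt0.nrow();
  NumericMatrix Wt = clone(Wt0);
  NumericMatrix H = clone(H0);
  NumericVector bu = clone(bu0);
  NumericVector bi = clone(bi0);
  std::vector<double> history;
  history.reserve(max_iter);
  bool converged = false;
  double prev_mse = R_PosInf;

  for (int iter = 0; iter < max_iter; ++iter) {
    IntegerVector ord = sample(n_obs, n_obs, false); // 1-based
    double sse = 0.0;
    for (int s = 0; s < n_obs; ++s) {
      int c = ord[s] - 1;
      int u = ui[c];
      int i = ii[c];
      double *pu = &Wt(0, u);
      double *qi = &H(0, i);
      double pred = mu + bu[u] + bi[i];
      for (int k = 0; k < f; ++k) pred += pu[k] * qi[k];
      double e = r[c] - pred;
      if (!std::isfinite(e))
        stop("non-finite training error at iteration %d; "
             "reduce the learning rate", iter + 1);
      sse += e * e;
      bi[i] += gamma * (e - lam_bi * bi[i]);
      bu[u] += gamma * (e - lam_bu * bu[u]);
      for (int k = 0; k < f; ++k) {
        double h = qi[k] + gamma * (e * pu[k] - lam_qi * qi[k]);
        qi[k] = h < 0.0 ? 0.0 : h;
      }
      for (int k = 0; k < f; ++k) {
        double w = pu[k] + gamma * (e * qi[k] - lam_pu * pu[k]);
        pu[k] = w < 0.0 ? 0.0 : w;
      }
      if (check_nonneg) {
        for (int k = 0; k < f; ++k)
          if (pu[k] < 0.0 || qi[k] < 0.0)
            stop("non-negativity violated during training");
      }
    }
    double mse = sse / n_obs;
    if (!std::isfinite(mse))
      stop("non-finite training error at iteration %d; "
           "reduce the learning rate", iter + 1);
    history.push_back(mse);
    if (std::fabs(prev_mse - mse) <= tol) {
      converged = true;
      break;
    }
    prev_mse = mse;
  }

  return List::create(_["Wt"] = Wt, _["H"] = H, _["b_u"] = bu, _["b_i"] = bi,
                      _["history"] = NumericVector(history.begin(), history.end()),
                      _["converged"] = converged, _["n_iter"] = (int)history.size());
}
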