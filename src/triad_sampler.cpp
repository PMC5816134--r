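#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Adaptive random-walk Metropolis sampler for the triad embedding model.
// Coordinates have independent normal(0, prior_sd) priors; each triad
// contributes a softmax-over-negative-distances likelihood term. One sweep
// updates every stimulus row in turn with a Gaussian proposal whose scale
// adapts toward ~30% acceptance during warmup. Uses R's RNG, so results
// are reproducible under set.seed().
//
// items: n_triads x 3 (1-based stimulus indices)
// chosen: 1 = pair (1,2), 2 = pair (1,3), 3 = pair (2,3)
// Returns thinned post-warmup draws as an (n_draws x n x d) array.
// [[Rcpp::export]]
List triad_rwm_cpp(NumericMatrix X0, IntegerMatrix items, IntegerVector chosen,
                   double temperature, double prior_sd,
                   int warmup, int n_draws, int thin, double step_init) {
  const int n = X0.nrow(), d = X0.ncol(), m = items.nrow();
  NumericMatrix X = clone(X0);

  std::vector< std::vector<int> > tri(n);
  for (int t = 0; t < m; t++)
    for (int j = 0; j < 3; j++) tri[items(t, j) - 1].push_back(t);

  auto distf = [&](int a, int b) {
    double s = 0.0;
    for (int k = 0; k < d; k++) { double df = X(a, k) - X(b, k); s += df * df; }
    return std::sqrt(s);
  };

  NumericMatrix D(m, 3);
  for (int t = 0; t < m; t++) {
    int i = items(t, 0) - 1, j = items(t, 1) - 1, k = items(t, 2) - 1;
    D(t, 0) = distf(i, j); D(t, 1) = distf(i, k); D(t, 2) = distf(j, k);
  }

  auto ll_triad = [&](double d1, double d2, double d3, int ch) {
    double a1 = -d1 / temperature, a2 = -d2 / temperature, a3 = -d3 / temperature;
    double mx = std::max(a1, std::max(a2, a3));
    double lse = mx + std::log(std::exp(a1 - mx) + std::exp(a2 - mx) +
                               std::exp(a3 - mx));
    double num = (ch == 1) ? a1 : (ch == 2) ? a2 : a3;
    return num - lse;
  };

  std::vector<double> step(n, step_init), acc(n, 0.0), cnt(n, 0.0), prop(d);
  const int total = warmup + n_draws * thin;
  NumericVector draws((R_xlen_t)n_draws * n * d);
  int save_i = 0;
  double prior_var2 = 2.0 * prior_sd * prior_sd;

  for (int sweep = 0; sweep < total; sweep++) {
    for (int s = 0; s < n; s++) {
      double dll = 0.0;
      for (int k = 0; k < d; k++) {
        prop[k] = X(s, k) + step[s] * norm_rand();
        dll += (X(s, k) * X(s, k) - prop[k] * prop[k]) / prior_var2;
      }
      const std::vector<int>& ts = tri[s];
      std::vector< std::array<double, 3> > newD(ts.size());
      for (size_t q = 0; q < ts.size(); q++) {
        int t = ts[q];
        int i = items(t, 0) - 1, j = items(t, 1) - 1, k = items(t, 2) - 1;
        double nd1 = D(t, 0), nd2 = D(t, 1), nd3 = D(t, 2);
        auto dist_to = [&](int other) {
          double ss = 0.0;
          for (int kk = 0; kk < d; kk++) {
            double df = prop[kk] - X(other, kk); ss += df * df;
          }
          return std::sqrt(ss);
        };
        if (i == s)      { nd1 = dist_to(j); nd2 = dist_to(k); }
        else if (j == s) { nd1 = dist_to(i); nd3 = dist_to(k); }
        else             { nd2 = dist_to(i); nd3 = dist_to(j); }
        newD[q] = { nd1, nd2, nd3 };
        dll += ll_triad(nd1, nd2, nd3, chosen[t]) -
               ll_triad(D(t, 0), D(t, 1), D(t, 2), chosen[t]);
      }
      cnt[s] += 1.0;
      if (std::log(unif_rand()) < dll) {
        acc[s] += 1.0;
        for (int k = 0; k < d; k++) X(s, k) = prop[k];
        for (size_t q = 0; q < ts.size(); q++) {
          int t = ts[q];
          D(t, 0) = newD[q][0]; D(t, 1) = newD[q][1]; D(t, 2) = newD[q][2];
        }
      }
    }
    if (sweep < warmup && (sweep + 1) % 25 == 0) {
      for (int s = 0; s < n; s++) {
        double rate = cnt[s] > 0 ? acc[s] / cnt[s] : 0.3;
        step[s] *= std::exp(1.5 * (rate - 0.3));
        step[s] = std::min(std::max(step[s], 1e-4), 10.0);
        acc[s] = 0.0; cnt[s] = 0.0;
      }
    }
    if (sweep == warmup - 1) {
      for (int s = 0; s < n; s++) { acc[s] = 0.0; cnt[s] = 0.0; }
    }
    if (sweep >= warmup && ((sweep - warmup + 1) % thin == 0)) {
      for (int s = 0; s < n; s++)
        for (int k = 0; k < d; k++)
          draws[save_i + (R_xlen_t)n_draws * (s + (R_xlen_t)n * k)] = X(s, k);
      save_i++;
    }
  }

  NumericVector acc_rate(n), step_out(n);
  for (int s = 0; s < n; s++) {
    acc_rate[s] = cnt[s] > 0 ? acc[s] / cnt[s] : NA_REAL;
    step_out[s] = step[s];
  }
  draws.attr("dim") = IntegerVector::create(n_draws, n, d);
  return List::create(_["draws"] = draws, _["acceptance"] = acc_rate,
                      _["step"] = step_out);
}
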