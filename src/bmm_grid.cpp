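#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exhaustive grid-search reference fitter for a 2-component Bernoulli
// mixture over 2 genomes.  Both components' per-genome probabilities are
// swept over a regular grid (clamped away from {0,1}); for each grid point
// the mixing weight is profiled by the EM fixed-point in pi alone (the
// log-likelihood is concave in pi for fixed thetas) plus an endpoint check.
// Intended as an independent oracle for tiny instances, not a fitter.
//
// counts: length-4 pattern counts for (x1,x2) = (0,0), (0,1), (1,0), (1,1)
// step:   grid resolution (e.g. 0.01)
// eps:    clamp applied to grid values
// [[Rcpp::export]]
List bmm_grid_search_2x2(NumericVector counts, double step, double eps,
                         int pi_iter) {
  const int P = 4;
  double n = 0.0;
  for (int p = 0; p < P; ++p) n += counts[p];

  const int ng = (int) std::floor(1.0 / step + 0.5) + 1;  // grid values 0..1
  std::vector<double> gv(ng);
  for (int i = 0; i < ng; ++i) {
    double v = i * step;
    if (v < eps) v = eps;
    if (v > 1.0 - eps) v = 1.0 - eps;
    gv[i] = v;
  }

  const int nc = ng * ng;  // one component's (a, b) combinations
  std::vector<double> q(nc * P);
  for (int ia = 0; ia < ng; ++ia) {
    for (int ib = 0; ib < ng; ++ib) {
      const int c = ia * ng + ib;
      const double a = gv[ia], b = gv[ib];
      q[c * P + 0] = (1 - a) * (1 - b);
      q[c * P + 1] = (1 - a) * b;
      q[c * P + 2] = a * (1 - b);
      q[c * P + 3] = a * b;
    }
  }

  // patterns with zero counts do not contribute
  int used[4]; int nu = 0;
  for (int p = 0; p < P; ++p) if (counts[p] > 0) used[nu++] = p;

  // pure-component log-likelihood per grid combo (the pi endpoints)
  std::vector<double> pure(nc);
  for (int c = 0; c < nc; ++c) {
    double s = 0.0;
    for (int u = 0; u < nu; ++u)
      s += counts[used[u]] * std::log(q[c * P + used[u]]);
    pure[c] = s;
  }

  double best_ll = -INFINITY, best_pi = 0.5;
  int best_i = 0, best_j = 0;
  // (i, j, pi) and (j, i, 1-pi) are the same mixture: j >= i is exhaustive
  for (int i = 0; i < nc; ++i) {
    const double* q1 = &q[i * P];
    for (int j = i; j < nc; ++j) {
      const double* q2 = &q[j * P];
      double pi = 0.5;
      for (int t = 0; t < pi_iter; ++t) {
        double s = 0.0;
        for (int u = 0; u < nu; ++u) {
          const int p = used[u];
          const double m1 = pi * q1[p];
          s += counts[p] * (m1 / (m1 + (1.0 - pi) * q2[p]));
        }
        s /= n;
        const double delta = s - pi;
        pi = s;
        if (delta < 1e-8 && delta > -1e-8) break;
      }
      double ll = 0.0;
      for (int u = 0; u < nu; ++u) {
        const int p = used[u];
        ll += counts[p] * std::log(pi * q1[p] + (1.0 - pi) * q2[p]);
      }
      // concave in pi, but also check the endpoints (pure components)
      double use_pi = pi;
      if (pure[j] > ll) { ll = pure[j]; use_pi = 0.0; }
      if (pure[i] > ll) { ll = pure[i]; use_pi = 1.0; }
      if (ll > best_ll) {
        best_ll = ll; best_pi = use_pi; best_i = i; best_j = j;
      }
    }
  }

  const int ng2 = ng;
  NumericVector theta1 = NumericVector::create(gv[best_i / ng2],
                                               gv[best_i % ng2]);
  NumericVector theta2 = NumericVector::create(gv[best_j / ng2],
                                               gv[best_j % ng2]);
  return List::create(_["logLik"] = best_ll, _["pi"] = best_pi,
                      _["theta1"] = theta1, _["theta2"] = theta2);
}
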