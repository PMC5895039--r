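#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Autoregressive choice-spike simulators.
//
// model: 1 = CM1  (instantaneous feedforward: the spike state enters the
//                  decision variable on the same trial)
//        2 = CM2  (postdecision feedback: the choice enters the spike state
//                  on the same trial)
//        3 = ICM1 (serial feedback: the *previous* choice enters the spike
//                  state)
//        4 = ICM2 (serial feedforward: the *previous* spike state enters the
//                  decision variable)
//
// Choice coding is +/-1 inside the recursions (0/1 outside); the spike state
// is a latent Gaussian AR(1) around mu, and counts are emitted by rounding
// at floor 0.  "coupling" is omega (CM1, ICM2) or gamma (CM2, ICM1).
// Draw order per trial (fixed so an R reference can reproduce the stream):
// spike innovation first, then decision noise; one uniform before the loop
// for the initial choice.

// [[Rcpp::export]]
List ar_simulate_cpp(int model, double alpha, double beta, double coupling,
                     double sigma1, double sigma2, double mu, int n) {
  IntegerVector choice(n);
  NumericVector count(n);
  double cbar_prev = (R::unif_rand() < 0.5) ? 1.0 : -1.0;
  double s_prev = mu;
  for (int t = 0; t < n; ++t) {
    double eps2 = R::norm_rand();
    double eps1 = R::norm_rand();
    double s_t, cbar;
    switch (model) {
    case 1: { // CM1
      s_t = mu + alpha * (s_prev - mu) + sigma2 * eps2;
      double m = coupling * (s_t - mu) + beta * cbar_prev + sigma1 * eps1;
      cbar = (m > 0) ? 1.0 : -1.0;
      break;
    }
    case 2: { // CM2
      double m = beta * cbar_prev + sigma1 * eps1;
      cbar = (m > 0) ? 1.0 : -1.0;
      s_t = mu + alpha * (s_prev - mu) + coupling * cbar + sigma2 * eps2;
      break;
    }
    case 3: { // ICM1
      double m = beta * cbar_prev + sigma1 * eps1;
      cbar = (m > 0) ? 1.0 : -1.0;
      s_t = mu + alpha * (s_prev - mu) + coupling * cbar_prev + sigma2 * eps2;
      break;
    }
    default: { // ICM2
      double m = coupling * (s_prev - mu) + beta * cbar_prev + sigma1 * eps1;
      cbar = (m > 0) ? 1.0 : -1.0;
      s_t = mu + alpha * (s_prev - mu) + sigma2 * eps2;
      break;
    }
    }
    choice[t] = (cbar > 0) ? 1 : 0;
    double c = std::round(s_t);
    count[t] = (c < 0.0) ? 0.0 : c;
    s_prev = s_t;
    cbar_prev = cbar;
  }
  return List::create(_["choice"] = choice, _["count"] = count);
}
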