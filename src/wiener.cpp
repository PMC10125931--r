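#include <Rcpp.h>
using namespace Rcpp;

// First-passage simulation of a scaled Wiener process with drift between two
// absorbing boundaries (lower 0, upper a), Euler-Maruyama with step dt:
//   X <- X + v*dt + sigma*sqrt(dt)*N(0,1)
// Absorption at >= a is a correct response, at <= 0 an error; the absorption
// step times dt is the decision time, to which the non-decision time t_er is
// added.  Trials still unabsorbed after max_steps get rt = NA (the R wrapper
// decides whether that is an error or a dropped trial).
//
// Draws come from R's RNG (norm_rand), so set.seed() in R makes the whole
// simulation reproducible and n trials consume the stream exactly as n
// successive single-trial calls would.

// [[Rcpp::export]]
List wiener_trials_cpp(int n, double v, double a, double start, double sigma,
                       double t_er, double dt, int max_steps) {
  NumericVector rt(n);
  LogicalVector correct(n);
  const double drift = v * dt;
  const double spread = sigma * std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = start;
    int step = 0;
    int outcome = NA_LOGICAL;
    while (step < max_steps) {
      x += drift + spread * norm_rand();
      ++step;
      if (x >= a) { outcome = TRUE; break; }
      if (x <= 0.0) { outcome = FALSE; break; }
    }
    if (outcome == NA_LOGICAL) {
      rt[i] = NA_REAL;
      correct[i] = NA_LOGICAL;
    } else {
      rt[i] = step * dt + t_er;
      correct[i] = (outcome == TRUE);
    }
  }
  return List::create(_["rt"] = rt, _["correct"] = correct);
}
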