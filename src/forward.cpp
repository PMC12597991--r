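#include <Rcpp.h>
using namespace Rcpp;

// Forward algorithm over the 8-state hidden Markov model, one capture
// history per row. The likelihood conditions on first capture: at the birth
// occasion the state is J (index 0) with probability one and the observed
// event (code 1) contributes nothing. Each later occasion applies the
// age-indexed transition product M[, , age] (phi %*% psi, age measured at
// the occasion being left) and masks by the event-probability column of the
// year-indexed event matrix E[, , year]. Probabilities are renormalized at
// every step and accumulated on the log scale, so histories of 60+ occasions
// do not underflow.
//
// events: n x T integer matrix of codes 0..5, NA (or any negative) before
//   birth; birth: 1-based birth column per individual; M: 8 x 8 x n_ages
//   (age 0 first); E: 8 x 6 x T.
// Returns the per-individual log-likelihood contribution; a history that is
// impossible under theta yields -Inf.
// [[Rcpp::export]]
NumericVector forward_loglik_cpp(IntegerMatrix events, IntegerVector birth,
                                 NumericVector M, NumericVector E,
                                 int n_ages) {
  const int n = events.nrow();
  const int T = events.ncol();
  NumericVector out(n);
  double alpha[8], anew[8];

  for (int i = 0; i < n; ++i) {
    const int b = birth[i] - 1; // 0-based birth column
    double ll = 0.0;
    for (int s = 0; s < 8; ++s) alpha[s] = 0.0;
    alpha[0] = 1.0; // mass one on J at birth
    if (events(i, b) != 1) {
      out[i] = R_NegInf; // conditioning requires a juvenile event at birth
      continue;
    }
    bool dead_path = false;
    for (int t = b + 1; t < T; ++t) {
      const int ev = events(i, t);
      if (ev == NA_INTEGER || ev < 0 || ev > 5) {
        out[i] = NA_REAL;
        dead_path = true;
        break;
      }
      int age = t - 1 - b; // age at the occasion being left
      if (age >= n_ages) age = n_ages - 1;
      const double *m = &M[64 * age];
      const double *e = &E[48 * t + 8 * ev];
      double tot = 0.0;
      for (int j = 0; j < 8; ++j) {
        double acc = 0.0;
        for (int s = 0; s < 8; ++s) acc += alpha[s] * m[s + 8 * j];
        acc *= e[j];
        anew[j] = acc;
        tot += acc;
      }
      if (!(tot > 0.0)) {
        out[i] = R_NegInf;
        dead_path = true;
        break;
      }
      ll += std::log(tot);
      for (int j = 0; j < 8; ++j) alpha[j] = anew[j] / tot;
    }
    if (!dead_path) out[i] = ll;
  }
  return out;
}
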