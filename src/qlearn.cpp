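#include <Rcpp.h>
using namespace Rcpp;

// Temporal-difference training loop for the two-action linear Q model.
// Action 0 = predict-patient, action 1 = predict-control; y[i] = 1 for
// patient. One episode = one Fisher-Yates shuffle of the training set;
// the bootstrap term is dropped at the episode's terminal sample. Epsilon
// decays linearly from epsilon0 to 0 across epochs. All randomness comes
// from R's RNG (deterministic under set.seed()).
// [[Rcpp::export]]
NumericMatrix qlearn_train_cpp(NumericMatrix X, IntegerVector y, double gamma,
                               double alpha, int epochs, double epsilon0) {
  const int n = X.nrow();
  const int p = X.ncol();
  if (y.size() != n) stop("one label per row required");

  NumericMatrix w(2, p + 1);  // zero-initialised; column p is the bias
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;

  auto qvalue = [&](int row, int a) {
    double q = w(a, p);
    for (int f = 0; f < p; ++f) q += w(a, f) * X(row, f);
    return q;
  };

  for (int e = 0; e < epochs; ++e) {
    const double eps =
        (epochs > 1) ? epsilon0 * (1.0 - (double)e / (epochs - 1)) : 0.0;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    for (int t = 0; t < n; ++t) {
      const int i = ord[t];
      const double q0 = qvalue(i, 0), q1 = qvalue(i, 1);
      int a;
      if (unif_rand() < eps)
        a = (unif_rand() < 0.5) ? 0 : 1;
      else
        a = (q0 > q1) ? 0 : 1;  // tie -> predict-control
      const double r =
          ((a == 0 && y[i] == 1) || (a == 1 && y[i] == 0)) ? 1.0 : -1.0;
      double target = r;
      if (t < n - 1) {
        const int nx = ord[t + 1];
        target += gamma * std::max(qvalue(nx, 0), qvalue(nx, 1));
      }
      const double delta = target - ((a == 0) ? q0 : q1);
      for (int f = 0; f < p; ++f) w(a, f) += alpha * delta * X(i, f);
      w(a, p) += alpha * delta;
    }
  }
  return w;
}
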