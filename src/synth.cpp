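#include <Rcpp.h>
using namespace Rcpp;

// Synthesize per-voxel BOLD series: baseline + amplitude-scaled sum of
// sinusoids + AR(1) noise (marginal SD ar_sd) + white noise + a per-volume
// additive artifact term. Noise is drawn from R's RNG so results are
// reproducible under set.seed(); the draw count does not depend on `amp`,
// which keeps two simulations that differ only in planted amplitudes on the
// same RNG stream.
// [[Rcpp::export]]
NumericMatrix synth_bold_cpp(NumericVector amp, NumericMatrix phases,
                             NumericVector omega, NumericVector tsec,
                             double baseline, double ar_coef, double ar_sd,
                             double white_sd, NumericVector extra) {
  const int V = amp.size();
  const int T = tsec.size();
  const int K = omega.size();
  if (phases.nrow() != V || phases.ncol() != K)
    stop("phase matrix must be voxels x frequencies");
  if (extra.size() != T) stop("artifact vector must have one entry per volume");

  NumericMatrix out(V, T);
  const double innov_sd =
      (ar_sd > 0.0) ? ar_sd * std::sqrt(1.0 - ar_coef * ar_coef) : 0.0;

  for (int v = 0; v < V; ++v) {
    double ar = (ar_sd > 0.0) ? norm_rand() * ar_sd : 0.0;
    const bool has_osc = amp[v] != 0.0;
    for (int t = 0; t < T; ++t) {
      if (t > 0 && ar_sd > 0.0) ar = ar_coef * ar + norm_rand() * innov_sd;
      double s = baseline + ar + extra[t];
      if (white_sd > 0.0) s += norm_rand() * white_sd;
      if (has_osc) {
        double osc = 0.0;
        for (int k = 0; k < K; ++k)
          osc += std::sin(omega[k] * tsec[t] + phases(v, k));
        s += amp[v] * osc;
      }
      out(v, t) = s;
    }
  }
  return out;
}
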