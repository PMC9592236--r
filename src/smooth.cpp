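#include <Rcpp.h>
using namespace Rcpp;

// Separable convolution of a flattened 3D/4D array along one spatial axis
// (0-based `axis` < 3). Boundaries are truncated (kernel mass outside the
// grid is dropped), matching the ratio-renormalised masked smoothing that
// divides by the convolved mask.
// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector a, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nd = dim.size();
  if (axis < 0 || axis > 2 || nd < 3) stop("axis must index a spatial dim");
  const int n = dim[axis];
  const int L = (kernel.size() - 1) / 2;
  if (kernel.size() != 2 * L + 1) stop("kernel must have odd length");

  R_xlen_t inner = 1, outer = 1;
  for (int i = 0; i < axis; ++i) inner *= dim[i];
  for (int i = axis + 1; i < nd; ++i) outer *= dim[i];

  NumericVector out(a.size());
  std::vector<double> line(n);
  for (R_xlen_t o = 0; o < outer; ++o) {
    const R_xlen_t block = o * n * inner;
    for (R_xlen_t in = 0; in < inner; ++in) {
      const double* src = &a[block + in];
      for (int i = 0; i < n; ++i) line[i] = src[(R_xlen_t)i * inner];
      double* dst = &out[block + in];
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        const int lo = std::max(0, i - L), hi = std::min(n - 1, i + L);
        for (int j = lo; j <= hi; ++j) s += kernel[j - i + L] * line[j];
        dst[(R_xlen_t)i * inner] = s;
      }
    }
  }
  return out;
}
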