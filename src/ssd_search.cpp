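#include <Rcpp.h>
using namespace Rcpp;

// Mean squared RGB difference between `patch` and the same-sized window of
// `frame` anchored (top-left, 0-based) at each candidate position.
// `frame` is an H x W x 3 array in R's column-major layout; candidates are
// given as 0-based top-left row/column offsets.
// [[Rcpp::export]]
NumericVector ssd_search_cpp(NumericVector frame, int H, int W,
                             NumericVector patch, int ph, int pw,
                             IntegerVector top, IntegerVector left) {
  const int n = top.size();
  NumericVector out(n);
  const double *fr = frame.begin();
  const double *pa = patch.begin();
  const double norm = 1.0 / (3.0 * ph * pw);
  for (int k = 0; k < n; ++k) {
    const int r0 = top[k], c0 = left[k];
    double acc = 0.0;
    for (int ch = 0; ch < 3; ++ch) {
      const double *fch = fr + (size_t)ch * H * W;
      const double *pch = pa + (size_t)ch * ph * pw;
      for (int c = 0; c < pw; ++c) {
        const double *fcol = fch + (size_t)(c0 + c) * H + r0;
        const double *pcol = pch + (size_t)c * ph;
        for (int r = 0; r < ph; ++r) {
          const double d = fcol[r] - pcol[r];
          acc += d * d;
        }
      }
    }
    out[k] = acc * norm;
  }
  return out;
}
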