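#include <Rcpp.h>
using namespace Rcpp;

// Grayscale morphological reconstruction by dilation of `marker` under
// `mask` (marker <= mask pointwise), 8-connected, by alternating raster
// scans until stabilization (the sequential reconstruction algorithm).
// [[Rcpp::export]]
NumericMatrix reconstruct_dilation_cpp(NumericMatrix marker, NumericMatrix mask) {
  const int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc) stop("marker/mask shape mismatch");
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr * nc; ++i)
    out[i] = std::min(marker[i], mask[i]);

  bool changed = true;
  int pass = 0;
  while (changed && pass < 2000) {
    changed = false;
    ++pass;
    // forward: neighbors already visited in column-major order
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        double v = out(r, c);
        if (r > 0) v = std::max(v, out(r - 1, c));
        if (c > 0) {
          v = std::max(v, out(r, c - 1));
          if (r > 0) v = std::max(v, out(r - 1, c - 1));
          if (r < nr - 1) v = std::max(v, out(r + 1, c - 1));
        }
        v = std::min(v, mask(r, c));
        if (v > out(r, c)) { out(r, c) = v; changed = true; }
      }
    }
    // backward
    for (int c = nc - 1; c >= 0; --c) {
      for (int r = nr - 1; r >= 0; --r) {
        double v = out(r, c);
        if (r < nr - 1) v = std::max(v, out(r + 1, c));
        if (c < nc - 1) {
          v = std::max(v, out(r, c + 1));
          if (r < nr - 1) v = std::max(v, out(r + 1, c + 1));
          if (r > 0) v = std::max(v, out(r - 1, c + 1));
        }
        v = std::min(v, mask(r, c));
        if (v > out(r, c)) { out(r, c) = v; changed = true; }
      }
    }
  }
  return out;
}
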