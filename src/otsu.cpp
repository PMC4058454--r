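#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive maximizer of the between-class variance over ordered k-tuples
// of histogram cut points. `counts` is the occupancy of B equal-width bins;
// a cut point T assigns bins 1..T to the class below it. Ties are resolved
// to the lexicographically smallest tuple by strict-improvement updates in
// ascending scan order. Returns 1-based bin indices of the k cut points.
// [[Rcpp::export]]
IntegerVector otsu_thresholds_cpp(IntegerVector counts, int k) {
  const int B = counts.size();
  if (k < 1 || k > 3) stop("k must be in 1..3");
  if (B < k + 1) stop("histogram too short");
  std::vector<double> w(B + 1, 0.0), m(B + 1, 0.0);
  for (int b = 1; b <= B; ++b) {
    w[b] = w[b - 1] + counts[b - 1];
    m[b] = m[b - 1] + (double)counts[b - 1] * b;
  }
  const double W = w[B];
  if (W <= 0) stop("empty histogram");
  const double mu = m[B] / W;

  // contribution w_c (mu_c - mu)^2 of the class spanning bins (a, b]
  auto seg = [&](int a, int b) -> double {
    double wv = w[b] - w[a];
    if (wv <= 0) return 0.0;
    double d = (m[b] - m[a]) / wv - mu;
    return wv * d * d;
  };

  double best = -1.0;
  IntegerVector out(k);
  if (k == 1) {
    for (int t1 = 1; t1 <= B - 1; ++t1) {
      double v = seg(0, t1) + seg(t1, B);
      if (v > best) { best = v; out[0] = t1; }
    }
  } else if (k == 2) {
    for (int t1 = 1; t1 <= B - 2; ++t1) {
      double s1 = seg(0, t1);
      for (int t2 = t1 + 1; t2 <= B - 1; ++t2) {
        double v = s1 + seg(t1, t2) + seg(t2, B);
        if (v > best) { best = v; out[0] = t1; out[1] = t2; }
      }
    }
  } else {
    for (int t1 = 1; t1 <= B - 3; ++t1) {
      double s1 = seg(0, t1);
      for (int t2 = t1 + 1; t2 <= B - 2; ++t2) {
        double s2 = s1 + seg(t1, t2);
        for (int t3 = t2 + 1; t3 <= B - 1; ++t3) {
          double v = s2 + seg(t2, t3) + seg(t3, B);
          if (v > best) { best = v; out[0] = t1; out[1] = t2; out[2] = t3; }
        }
      }
    }
  }
  return out;
}
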