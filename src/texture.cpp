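#include <Rcpp.h>
using namespace Rcpp;

// symmetric (edge-inclusive) reflection of an out-of-range 0-based index
static inline int reflectIdx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// windowed population variance with symmetric border padding
// [[Rcpp::export]]
NumericMatrix localContrastC(NumericMatrix x, int w) {
  int nr = x.nrow(), nc = x.ncol(), h = w / 2;
  double N = (double)w * (double)w;
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int dc = -h; dc <= h; ++dc) {
        int cc = reflectIdx(c + dc, nc);
        for (int dr = -h; dr <= h; ++dr)
          s += x(reflectIdx(r + dr, nr), cc);
      }
      double mu = s / N, acc = 0.0;
      for (int dc = -h; dc <= h; ++dc) {
        int cc = reflectIdx(c + dc, nc);
        for (int dr = -h; dr <= h; ++dr) {
          double d = x(reflectIdx(r + dr, nr), cc) - mu;
          acc += d * d;
        }
      }
      out(r, c) = acc / N;
    }
  }
  return out;
}

// windowed Shannon entropy (bits) of pre-quantised levels 0..L-1,
// eps added inside the logarithm, symmetric border padding
// [[Rcpp::export]]
NumericMatrix localEntropyC(IntegerMatrix q, int w, int L, double eps) {
  int nr = q.nrow(), nc = q.ncol(), h = w / 2;
  double N = (double)w * (double)w;
  NumericMatrix out(nr, nc);
  std::vector<int> cnt(L, 0);
  std::vector<int> touched;
  touched.reserve(w * w);
  const double log2e = 1.0 / std::log(2.0);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      touched.clear();
      for (int dc = -h; dc <= h; ++dc) {
        int cc = reflectIdx(c + dc, nc);
        for (int dr = -h; dr <= h; ++dr) {
          int k = q(reflectIdx(r + dr, nr), cc);
          if (cnt[k] == 0) touched.push_back(k);
          cnt[k]++;
        }
      }
      double H = 0.0;
      for (size_t t = 0; t < touched.size(); ++t) {
        double p = cnt[touched[t]] / N;
        H -= p * std::log(p + eps) * log2e;
        cnt[touched[t]] = 0;
      }
      out(r, c) = H;
    }
  }
  return out;
}
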