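#include <Rcpp.h>
using namespace Rcpp;

// One draw from the multivariate hypergeometric distribution with urn
// composition `counts` and `size` balls drawn without replacement.
// Sequential conditional scheme: element i gets a univariate hypergeometric
// draw given what the remaining elements can still supply. Uses R's RNG so
// results are reproducible under set.seed().
static void draw_mvhyper(const IntegerVector &counts, int size, int *out) {
  const int N = counts.size();
  double rem = 0.0;
  for (int i = 0; i < N; ++i) rem += counts[i];
  int s = size;
  for (int i = 0; i < N; ++i) {
    int x = 0;
    if (s > 0 && counts[i] > 0) {
      const double nr = counts[i];
      const double nb = rem - nr;
      x = (int)::Rf_rhyper(nr, nb, (double)s);
    }
    out[i] = x;
    s -= x;
    rem -= counts[i];
  }
}

// [[Rcpp::export]]
IntegerVector cpp_sample_counts(IntegerVector counts, int size) {
  IntegerVector out(counts.size());
  draw_mvhyper(counts, size, INTEGER(out));
  return out;
}

// k draws stacked as a k x N matrix (small problems only; memory guarded in R)
// [[Rcpp::export]]
IntegerMatrix cpp_sample_matrix(IntegerVector counts, int size, int k) {
  const int N = counts.size();
  IntegerMatrix out(k, N);
  std::vector<int> buf(N);
  for (int r = 0; r < k; ++r) {
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
    draw_mvhyper(counts, size, buf.data());
    for (int i = 0; i < N; ++i) out(r, i) = buf[i];
  }
  return out;
}

// k draws summarised without storing them: per-element min, max, sum and a
// tally of how often each achievable count 0..n_i was observed. The tally is
// laid out contiguously with offsets cumsum(c(0, counts + 1)).
// [[Rcpp::export]]
List cpp_band_stats(IntegerVector counts, int size, int k) {
  const int N = counts.size();
  std::vector<double> off(N + 1, 0.0);
  for (int i = 0; i < N; ++i) off[i + 1] = off[i] + counts[i] + 1;
  const R_xlen_t tally_len = (R_xlen_t)off[N];

  IntegerVector lo(N), hi(N);
  NumericVector sums(N);
  NumericVector tally(tally_len);
  std::vector<int> buf(N);

  for (int r = 0; r < k; ++r) {
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
    draw_mvhyper(counts, size, buf.data());
    for (int i = 0; i < N; ++i) {
      const int x = buf[i];
      if (r == 0 || x < lo[i]) lo[i] = x;
      if (r == 0 || x > hi[i]) hi[i] = x;
      sums[i] += x;
      tally[(R_xlen_t)off[i] + x] += 1.0;
    }
  }
  return List::create(_["lower"] = lo, _["upper"] = hi,
                      _["sums"] = sums, _["tally"] = tally);
}
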