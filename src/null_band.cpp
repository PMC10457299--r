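#include <Rcpp.h>
using namespace Rcpp;

// Two-stage binomial null for one window of a QTL-seq scan. For each
// replicate, each bulk draws the number of ALT-carrying lines among its
// `bulk_size` pooled RILs ~ Binomial(k, 1/2) (lines treated as homozygous)
// and each member site then draws ALT reads ~ Binomial(observed depth, p)
// with p = count / k; the replicate statistic is the unweighted mean over
// member sites of delta = ALT fraction(high) - ALT fraction(low).
//
// `shared_lines` selects how the line draw relates to the window's sites:
// true  — one line configuration per bulk per replicate, shared by every
//         member site (the tight-linkage limit: a 1-Mbp window spans only
//         a few cM, so its sites segregate as one block);
// false — an independent line configuration per site (unlinked sites).
// The two coincide for single-site windows. Uses R's RNG, so set.seed()
// governs the draws.

// [[Rcpp::export]]
NumericVector null_window_deltas(IntegerVector depth_high,
                                 IntegerVector depth_low,
                                 int bulk_size, int n_rep,
                                 bool shared_lines = true) {
  int m = depth_high.size();
  if (m != depth_low.size())
    stop("depth vectors differ in length");
  if (bulk_size <= 0) stop("bulk_size must be positive");
  if (m == 0) stop("window has no member sites");
  NumericVector out(n_rep);
  double k = (double) bulk_size;
  for (int r = 0; r < n_rep; ++r) {
    double acc = 0.0;
    double ph = 0.0, pl = 0.0;
    if (shared_lines) {
      ph = R::rbinom(k, 0.5) / k;
      pl = R::rbinom(k, 0.5) / k;
    }
    for (int j = 0; j < m; ++j) {
      if (!shared_lines) {
        ph = R::rbinom(k, 0.5) / k;
        pl = R::rbinom(k, 0.5) / k;
      }
      double ah = R::rbinom((double) depth_high[j], ph);
      double al = R::rbinom((double) depth_low[j], pl);
      acc += ah / depth_high[j] - al / depth_low[j];
    }
    out[r] = acc / m;
  }
  return out;
}
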