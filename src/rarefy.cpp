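#include <Rcpp.h>
using namespace Rcpp;

// Multivariate hypergeometric draw: subsample `depth` reads without
// replacement from the read pool described by integer counts `x`.
// Sequential conditional draws; uses R's RNG so set.seed() governs it.
// [[Rcpp::export(name = ".rarefy_one")]]
IntegerVector rarefy_one(IntegerVector x, int depth) {
  const int S = x.size();
  double total = 0.0;
  for (int i = 0; i < S; ++i) {
    if (x[i] == NA_INTEGER || x[i] < 0)
      stop("counts must be non-negative integers");
    total += x[i];
  }
  if (depth < 1)
    stop("rarefaction depth must be >= 1");
  if (total < depth)
    stop("rarefaction depth exceeds column total");
  IntegerVector out(S);
  double rest = total;
  double need = depth;
  for (int i = 0; i < S; ++i) {
    if (need <= 0) break;
    rest -= x[i];
    double k = ::Rf_rhyper((double) x[i], rest, need);
    out[i] = (int) k;
    need -= k;
  }
  return out;
}

// Mean post-threshold richness of `repeats` independent rarefactions of one
// column.  Threshold t: a taxon needs >= max(t, 1) reads to count.
// [[Rcpp::export(name = ".mean_rarefied_richness")]]
double mean_rarefied_richness(IntegerVector x, int depth, int threshold,
                              int repeats) {
  if (repeats < 1) stop("repeats must be >= 1");
  const int S = x.size();
  const int keep = threshold > 1 ? threshold : 1;
  double total = 0.0;
  for (int i = 0; i < S; ++i) total += x[i];
  if (total < depth) stop("rarefaction depth exceeds column total");
  double acc = 0.0;
  for (int r = 0; r < repeats; ++r) {
    double rest = total, need = depth;
    int rich = 0;
    for (int i = 0; i < S; ++i) {
      if (need <= 0) break;
      rest -= x[i];
      double k = ::Rf_rhyper((double) x[i], rest, need);
      if (k >= keep) ++rich;
      need -= k;
    }
    acc += rich;
  }
  return acc / repeats;
}
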