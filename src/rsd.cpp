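#include <Rcpp.h>
using namespace Rcpp;

// Random segmental duplication growth. One event: pick a segment length l
// uniformly on [1, min(2*d_mean, L)], a source start uniformly on [0, L - l],
// copy the segment and insert the copy at a site uniform on [0, L]. Repeat
// until the sequence length first reaches the target. Draws come from R's RNG
// stream (RNGScope via Rcpp attributes), so set.seed() on the R side makes the
// whole growth reproducible.
//
// [[Rcpp::export]]
List rsd_grow_cpp(std::string seq, double d_mean, double target) {
  if (d_mean < 1.0) stop("d_mean must be >= 1");
  if ((double)seq.size() >= target)
    stop("initial sequence already at or beyond target length");
  std::string s(seq);
  std::vector<int> src, len, ins, newlen;
  while ((double)s.size() < target) {
    int L = (int)s.size();
    double dmax = std::min(2.0 * d_mean, (double)L);
    int l = 1 + (int)(unif_rand() * dmax);
    if (l > (int)dmax) l = (int)dmax;   // unif_rand() can return 1.0
    int start = (int)(unif_rand() * (double)(L - l + 1));
    if (start > L - l) start = L - l;
    int at = (int)(unif_rand() * (double)(L + 1));
    if (at > L) at = L;
    std::string segment = s.substr((size_t)start, (size_t)l);
    s.insert((size_t)at, segment);
    src.push_back(start);
    len.push_back(l);
    ins.push_back(at);
    newlen.push_back((int)s.size());
  }
  size_t n = src.size();
  IntegerMatrix log((int)n, 4);
  for (size_t i = 0; i < n; ++i) {
    log((int)i, 0) = src[i];
    log((int)i, 1) = len[i];
    log((int)i, 2) = ins[i];
    log((int)i, 3) = newlen[i];
  }
  colnames(log) = CharacterVector::create("source_start", "length",
                                          "insert_at", "length_after");
  return List::create(_["residues"] = s, _["log"] = log);
}
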