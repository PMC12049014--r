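// k-mer encoding and anchor chaining support.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Big-endian 2-bit codes (A=0, C=1, G=2, T=3; first base most significant) at
// positions 0, step, 2*step, ... with pos + k <= length. NA for k-mers
// containing any non-ACGT symbol.
// [[Rcpp::export(name = ".kmer_codes_cpp")]]
IntegerVector kmer_codes_cpp(std::string seq, int k, int step) {
  int L = (int)seq.size();
  if (k < 1) stop("k must be >= 1");
  if (step < 1) stop("step must be >= 1");
  if (L < k) return IntegerVector(0);
  int n = (L - k) / step + 1;
  IntegerVector out(n);
  for (int w = 0; w < n; ++w) {
    int pos = w * step;
    long code = 0;
    bool ok = true;
    for (int q = 0; q < k; ++q) {
      int b;
      switch (seq[pos + q]) {
      case 'A': b = 0; break;
      case 'C': b = 1; break;
      case 'G': b = 2; break;
      case 'T': b = 3; break;
      default: b = -1;
      }
      if (b < 0) { ok = false; break; }
      code = code * 4 + b;
    }
    out[w] = ok ? (int)code : NA_INTEGER;
  }
  return out;
}

// Collinear anchor chaining: node reward k*match; edge u->v allowed iff
// v.read >= u.read + k and v.ref >= u.ref + k; edge cost is the 2-piece gap
// cost of |d_read - d_ref| when the diagonals differ, 0 otherwise. Anchors
// must arrive sorted by (read_pos, ref_pos). Ties prefer more anchors, then
// the chain starting leftmost on the reference.
// [[Rcpp::export(name = ".chain_anchors_cpp")]]
List chain_anchors_cpp(IntegerVector read_pos, IntegerVector ref_pos, int k,
                       int match, int po, int pe, int po2, int pe2) {
  int n = read_pos.size();
  if (n == 0)
    return List::create(_["chain"] = IntegerVector(0), _["score"] = 0);
  std::vector<long> score(n);
  std::vector<int> cnt(n), parent(n), start_ref(n);
  long node = (long)k * match;
  for (int v = 0; v < n; ++v) {
    score[v] = node; cnt[v] = 1; parent[v] = -1; start_ref[v] = ref_pos[v];
    for (int u = 0; u < v; ++u) {
      long dq = (long)read_pos[v] - read_pos[u] - k;
      long dr = (long)ref_pos[v] - ref_pos[u] - k;
      if (dq < 0 || dr < 0) continue;
      long cost = 0;
      if (dq != dr) {
        long g = dq > dr ? dq - dr : dr - dq;
        long c1 = po + g * pe, c2 = po2 + g * pe2;
        cost = c1 < c2 ? c1 : c2;
      }
      long cand = score[u] + node - cost;
      bool better = cand > score[v] ||
        (cand == score[v] && (cnt[u] + 1 > cnt[v] ||
          (cnt[u] + 1 == cnt[v] && start_ref[u] < start_ref[v])));
      if (better) {
        score[v] = cand; cnt[v] = cnt[u] + 1; parent[v] = u;
        start_ref[v] = start_ref[u];
      }
    }
  }
  int best = 0;
  for (int v = 1; v < n; ++v) {
    bool better = score[v] > score[best] ||
      (score[v] == score[best] && (cnt[v] > cnt[best] ||
        (cnt[v] == cnt[best] && start_ref[v] < start_ref[best])));
    if (better) best = v;
  }
  std::vector<int> chain;
  for (int v = best; v >= 0; v = parent[v]) chain.push_back(v + 1);
  IntegerVector out(chain.size());
  for (size_t q = 0; q < chain.size(); ++q)
    out[q] = chain[chain.size() - 1 - q];
  return List::create(_["chain"] = out, _["score"] = (double)score[best]);
}
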