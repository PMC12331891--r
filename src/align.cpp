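#include <Rcpp.h>
#include <unordered_set>
#include <cstdint>
#include <vector>
#include <string>
#include <cmath>

using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Myers (1999) bit-parallel approximate matching, Hyyro's formulation.
// Returns, for every end position j in `text` (1-based in R terms), the
// minimum edit distance of an occurrence of the whole `pattern` ending at j
// (match start in the text is free). Pattern length is limited to one
// machine word (64 bases), which covers primer anchors and the 34 bp
// loxPsym site.
// [[Rcpp::export]]
IntegerVector myers_end_dists(std::string pattern, std::string text) {
  const int m = (int) pattern.size();
  const int n = (int) text.size();
  if (m < 1 || m > 64) stop("pattern length must be between 1 and 64");
  uint64_t Peq[4] = {0, 0, 0, 0};
  for (int i = 0; i < m; ++i) {
    int b = base2bit(pattern[i]);
    if (b >= 0) Peq[b] |= (1ULL << i);
  }
  const uint64_t mask = (m == 64) ? ~0ULL : ((1ULL << m) - 1);
  const uint64_t high = 1ULL << (m - 1);
  uint64_t Pv = mask, Mv = 0;
  int score = m;
  IntegerVector out(n);
  for (int j = 0; j < n; ++j) {
    int b = base2bit(text[j]);
    uint64_t Eq = (b >= 0) ? Peq[b] : 0ULL;
    uint64_t Xv = Eq | Mv;
    uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
    uint64_t Ph = Mv | ~(Xh | Pv);
    uint64_t Mh = Pv & Xh;
    if (Ph & high) ++score;
    if (Mh & high) --score;
    // searching variant: D[0][j] = 0 for every j (free match start in
    // the text), so a zero bit is shifted in
    Ph = Ph << 1;
    Mh = Mh << 1;
    Pv = (Mh | ~(Xv | Ph)) & mask;
    Mv = (Ph & Xv) & mask;
    out[j] = score;
  }
  return out;
}

// Banded global (Needleman-Wunsch, unit cost) edit distance. The band is
// centred on the length-scaled diagonal, so it tolerates the net indel
// drift of noisy long reads; `band` is widened to at least the length
// difference plus one so an optimal path always fits when the stated band
// is generous enough. Returns Levenshtein distance.
// [[Rcpp::export]]
int banded_edit_distance(std::string a, std::string b, int band) {
  const int la = (int) a.size(), lb = (int) b.size();
  if (la == 0) return lb;
  if (lb == 0) return la;
  int diff = std::abs(la - lb);
  if (band < diff + 1) band = diff + 1;
  const int INF = 1 << 28;
  std::vector<int> prev((size_t) lb + 1, INF), cur((size_t) lb + 1, INF);
  int plo = 0, phi = std::min(lb, band);
  for (int j = plo; j <= phi; ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    int center = (int) std::lround((double) i * lb / la);
    int lo = std::max(0, center - band);
    int hi = std::min(lb, center + band);
    for (int j = lo; j <= hi; ++j) {
      int best = INF;
      if (j == 0) {
        best = i;
      } else {
        if (j - 1 >= plo && j - 1 <= phi && prev[j - 1] < INF) {
          int c = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
          if (c < best) best = c;
        }
        if (j >= plo && j <= phi && prev[j] < INF && prev[j] + 1 < best)
          best = prev[j] + 1;
        if (j - 1 >= lo && cur[j - 1] < INF && cur[j - 1] + 1 < best)
          best = cur[j - 1] + 1;
      }
      cur[j] = best;
    }
    for (int j = plo; j <= phi; ++j)
      if (j < lo || j > hi) prev[j] = INF;
    for (int j = lo; j <= hi; ++j) { prev[j] = cur[j]; cur[j] = INF; }
    plo = lo; phi = hi;
  }
  int res = (lb >= plo && lb <= phi) ? prev[lb] : INF;
  if (res >= INF) stop("band too narrow for these sequence lengths");
  return res;
}

// Number of k-mers of each sequence in `seqs` that occur (exactly) in
// `chunk`. Used as a fast vote to pick the candidate segment/strand for a
// read chunk before the banded alignment verifies it. k is limited to 31
// so a k-mer fits in a 2-bit-packed 64-bit word.
// [[Rcpp::export]]
IntegerVector kmer_hit_counts(std::string chunk, CharacterVector seqs, int k) {
  if (k < 4 || k > 31) stop("k must be between 4 and 31");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::unordered_set<uint64_t> kmers;
  kmers.reserve(chunk.size());
  uint64_t cur = 0;
  int valid = 0;
  for (size_t i = 0; i < chunk.size(); ++i) {
    int b = base2bit(chunk[i]);
    if (b < 0) { valid = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t) b) & mask;
    if (++valid >= k) kmers.insert(cur);
  }
  IntegerVector out(seqs.size());
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    int cnt = 0;
    cur = 0; valid = 0;
    for (size_t i = 0; i < seq.size(); ++i) {
      int b = base2bit(seq[i]);
      if (b < 0) { valid = 0; cur = 0; continue; }
      cur = ((cur << 2) | (uint64_t) b) & mask;
      if (++valid >= k && kmers.count(cur)) ++cnt;
    }
    out[s] = cnt;
  }
  return out;
}
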