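#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

// splitmix64 finalizer: the documented sketch hash. Seeded by XOR with a
// fixed constant derived from the user-visible seed (default 42) so sketches
// are reproducible across platforms and runs.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// 2-bit encoding with A<C<G<T so packed comparison == lexicographic
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;  // N or other ambiguity code
  }
}

// Enumerate canonical k-mers (lexicographic min of k-mer and its reverse
// complement), hash each, keep the s smallest distinct values. Hashes are
// truncated to the top 53 bits so they are exactly representable as R
// doubles; ordering and distinctness are preserved.
// [[Rcpp::export]]
NumericVector sketch_hashes_cpp(std::string seq, int k, int s, double seed) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if ((int)seq.size() < k) stop("sequence shorter than k");
  const uint64_t seed_mix = splitmix64((uint64_t)seed);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;  // run length of unambiguous bases ending here
  std::vector<uint64_t> keep;  // max-heap of the s smallest hashes
  std::vector<uint64_t> seen;  // membership check done on sorted copy later;
  // use a hash set for distinctness instead (sketch sizes are small)
  std::unordered_map<uint64_t, char> in_heap;
  for (size_t i = 0; i < seq.size(); ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    ++valid;
    if (valid < k) continue;
    uint64_t canon = std::min(fwd, rev);
    uint64_t h = splitmix64(canon ^ seed_mix) >> 11;  // 53-bit value
    if (in_heap.count(h)) continue;
    if ((int)keep.size() < s) {
      keep.push_back(h); in_heap[h] = 1;
      std::push_heap(keep.begin(), keep.end());
    } else if (h < keep.front()) {
      in_heap.erase(keep.front());
      std::pop_heap(keep.begin(), keep.end());
      keep.back() = h; in_heap[h] = 1;
      std::push_heap(keep.begin(), keep.end());
    }
  }
  std::sort(keep.begin(), keep.end());
  NumericVector out(keep.size());
  for (size_t i = 0; i < keep.size(); ++i) out[i] = (double)keep[i];
  return out;
}

// ---------------------------------------------------------------------------
// Fragment-based ANI: cut the query into non-overlapping fragments, anchor
// each by exact k-mer match (forward strand; substitutions only) into the
// reference, score ungapped identity at each candidate offset, keep the best.

struct IvMerge {
  // union length of half-open intervals
  static double union_len(std::vector<std::pair<int,int> >& iv) {
    if (iv.empty()) return 0.0;
    std::sort(iv.begin(), iv.end());
    long total = 0; int lo = iv[0].first, hi = iv[0].second;
    for (size_t i = 1; i < iv.size(); ++i) {
      if (iv[i].first > hi) { total += hi - lo; lo = iv[i].first; hi = iv[i].second; }
      else if (iv[i].second > hi) hi = iv[i].second;
    }
    total += hi - lo;
    return (double)total;
  }
};

// [[Rcpp::export]]
List fragment_ani_cpp(std::string query, std::string ref,
                      int fragment_length, double min_identity,
                      int anchor_k, int max_candidates) {
  if (query.empty() || ref.empty()) stop("empty sequence");
  if (anchor_k < 1 || anchor_k > 31) stop("anchor_k must be in [1, 31]");
  const int qlen = (int)query.size(), rlen = (int)ref.size();
  int flen = fragment_length;
  if (flen > qlen) flen = qlen;  // single fragment covering the whole query

  // index reference k-mers (forward strand)
  const uint64_t mask = (1ULL << (2 * anchor_k)) - 1;
  std::unordered_map<uint64_t, std::vector<int> > index;
  if (rlen >= anchor_k) {
    uint64_t w = 0; int valid = 0;
    for (int i = 0; i < rlen; ++i) {
      int c = base_code(ref[i]);
      if (c < 0) { valid = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)c) & mask;
      if (++valid >= anchor_k) index[w].push_back(i - anchor_k + 1);
    }
  }

  int n_frag = qlen / flen;
  if (n_frag == 0) n_frag = 1;
  int n_aligned = 0;
  double identity_sum = 0.0;
  std::vector<std::pair<int,int> > ref_iv;

  for (int f = 0; f < n_frag; ++f) {
    const int f0 = f * flen;
    const int fl = std::min(flen, qlen - f0);
    if (fl < anchor_k) break;
    // collect candidate offsets from anchor k-mers along the fragment
    std::vector<int> cand;
    uint64_t w = 0; int valid = 0;
    for (int i = f0; i < f0 + fl && (int)cand.size() < max_candidates; ++i) {
      int c = base_code(query[i]);
      if (c < 0) { valid = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)c) & mask;
      if (++valid < anchor_k) continue;
      std::unordered_map<uint64_t, std::vector<int> >::const_iterator it = index.find(w);
      if (it == index.end()) continue;
      const int qpos = i - anchor_k + 1;
      for (size_t j = 0; j < it->second.size() && (int)cand.size() < max_candidates; ++j)
        cand.push_back(it->second[j] - (qpos - f0));
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

    double best_id = -1.0; int best_off = 0, best_lo = 0, best_hi = 0;
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      int off = cand[ci];
      int lo = std::max(0, off), hi = std::min(rlen, off + fl);
      int overlap = hi - lo;
      if (overlap < fl / 2 || overlap < anchor_k) continue;
      int matches = 0;
      for (int p = lo; p < hi; ++p) {
        int qc = base_code(query[p - off + f0]);
        int rc = base_code(ref[p]);
        if (qc >= 0 && qc == rc) ++matches;
      }
      double id = (double)matches / (double)overlap;
      if (id > best_id) { best_id = id; best_off = off; best_lo = lo; best_hi = hi; }
    }
    if (best_id >= min_identity) {
      ++n_aligned;
      identity_sum += best_id;
      ref_iv.push_back(std::make_pair(best_lo, best_hi));
      (void)best_off;
    }
  }

  double ani = (n_aligned > 0) ? 100.0 * identity_sum / n_aligned : NA_REAL;
  double af_query = 100.0 * (double)n_aligned / (double)n_frag;
  double af_ref = 100.0 * IvMerge::union_len(ref_iv) / (double)rlen;
  return List::create(_["ani"] = ani,
                      _["af_query"] = af_query,
                      _["af_ref"] = af_ref,
                      _["n_fragments"] = n_frag,
                      _["n_aligned"] = n_aligned);
}
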