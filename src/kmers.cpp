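#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit DNA encoding; k is capped at 31 so a canonical k-mer fits in a
// uint64 (2k <= 62 bits).

static inline int base2code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct KmerIndex {
  int k;
  int nrefs;
  std::unordered_map<uint64_t, std::vector<int32_t> > map;
};

// Enumerate canonical k-mers of s; cb(pos, canon) called for every window
// free of non-ACGT characters. pos is 0-based.
template <typename F>
static void for_each_canonical(const char *s, int len, int k, F cb) {
  if (len < k) return;
  uint64_t fwd = 0, rev = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  int run = 0;
  for (int i = 0; i < len; ++i) {
    int c = base2code(s[i]);
    if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      cb(i - k + 1, canon);
    }
  }
}

// [[Rcpp::export(name = ".kmer_index_build")]]
SEXP kmer_index_build(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  KmerIndex *idx = new KmerIndex();
  idx->k = k;
  idx->nrefs = seqs.size();
  size_t total = 0;
  for (int r = 0; r < seqs.size(); ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    int len = LENGTH(STRING_ELT(seqs, r));
    for_each_canonical(s, len, k, [&](int, uint64_t canon) {
      std::vector<int32_t> &v = idx->map[canon];
      if (v.empty() || v.back() != (int32_t)(r + 1)) v.push_back(r + 1);
      ++total;
    });
  }
  if (idx->map.empty()) {
    delete idx;
    stop("no reference sequence is long enough to index at k=%d", k);
  }
  XPtr<KmerIndex> ptr(idx, true);
  ptr.attr("n_kmers") = (double)idx->map.size();
  ptr.attr("n_positions") = (double)total;
  return ptr;
}

// Classify queries against the index. For each query, per-reference
// hit_length is the number of query bases covered by >=1 matching k-mer
// (union of matched k-mer intervals). One output row per reference tied at
// the maximal hit_length; queries with no match get one row with ref 0.
// [[Rcpp::export(name = ".kmer_index_classify")]]
List kmer_index_classify(SEXP xp, CharacterVector seqs) {
  XPtr<KmerIndex> ptr(xp);
  KmerIndex *idx = ptr.get();
  const int k = idx->k;

  std::vector<int> out_query, out_ref, out_hitlen, out_qlen, out_nmatch;
  // per-ref running interval-union state, touched refs reset per query
  std::vector<int> last_end(idx->nrefs + 1, -1);
  std::vector<int> cov(idx->nrefs + 1, 0);
  std::vector<int> touched;

  for (int q = 0; q < seqs.size(); ++q) {
    const char *s = CHAR(STRING_ELT(seqs, q));
    int len = LENGTH(STRING_ELT(seqs, q));
    touched.clear();
    for_each_canonical(s, len, k, [&](int pos, uint64_t canon) {
      std::unordered_map<uint64_t, std::vector<int32_t> >::const_iterator it =
        idx->map.find(canon);
      if (it == idx->map.end()) return;
      for (size_t j = 0; j < it->second.size(); ++j) {
        int r = it->second[j];
        if (last_end[r] < 0) { touched.push_back(r); last_end[r] = 0; cov[r] = 0; }
        int start = pos > last_end[r] ? pos : last_end[r];
        int end = pos + k;
        if (end > start) cov[r] += end - start;
        if (end > last_end[r]) last_end[r] = end;
      }
    });
    int best = 0;
    for (size_t j = 0; j < touched.size(); ++j)
      if (cov[touched[j]] > best) best = cov[touched[j]];
    if (best == 0) {
      out_query.push_back(q + 1); out_ref.push_back(0);
      out_hitlen.push_back(0); out_qlen.push_back(len); out_nmatch.push_back(0);
    } else {
      std::vector<int> ties;
      for (size_t j = 0; j < touched.size(); ++j)
        if (cov[touched[j]] == best) ties.push_back(touched[j]);
      std::sort(ties.begin(), ties.end());
      for (size_t j = 0; j < ties.size(); ++j) {
        out_query.push_back(q + 1); out_ref.push_back(ties[j]);
        out_hitlen.push_back(best); out_qlen.push_back(len);
        out_nmatch.push_back((int)ties.size());
      }
    }
    for (size_t j = 0; j < touched.size(); ++j) last_end[touched[j]] = -1;
  }
  return List::create(_["query"] = out_query, _["ref"] = out_ref,
                      _["hit_length"] = out_hitlen, _["query_length"] = out_qlen,
                      _["num_matches"] = out_nmatch);
}

// [[Rcpp::export(name = ".kmer_index_k")]]
int kmer_index_k(SEXP xp) {
  XPtr<KmerIndex> ptr(xp);
  return ptr->k;
}

static uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3 - (code & 3));
    code >>= 2;
  }
  return rc;
}

// L1-normalized canonical k-mer frequency matrix (one row per sequence).
// Columns are all canonical k-mers in lexicographic code order.
// [[Rcpp::export(name = ".canonical_kmer_freq")]]
NumericMatrix canonical_kmer_freq(CharacterVector seqs, int k) {
  if (k < 1 || k > 8) stop("composition k must be in 1..8");
  const uint64_t nk = 1ULL << (2 * k);
  std::vector<int> colmap(nk, -1);
  std::vector<uint64_t> canon_codes;
  for (uint64_t code = 0; code < nk; ++code) {
    uint64_t rc = revcomp_code(code, k);
    uint64_t canon = code < rc ? code : rc;
    if (canon == code) {
      colmap[code] = (int)canon_codes.size();
      canon_codes.push_back(code);
    }
  }
  for (uint64_t code = 0; code < nk; ++code)
    if (colmap[code] < 0) colmap[code] = colmap[revcomp_code(code, k)];

  NumericMatrix out(seqs.size(), (int)canon_codes.size());
  for (int q = 0; q < seqs.size(); ++q) {
    const char *s = CHAR(STRING_ELT(seqs, q));
    int len = LENGTH(STRING_ELT(seqs, q));
    double total = 0;
    for_each_canonical(s, len, k, [&](int, uint64_t canon) {
      out(q, colmap[canon]) += 1.0;
      total += 1.0;
    });
    if (total > 0)
      for (int j = 0; j < out.ncol(); ++j) out(q, j) /= total;
  }
  CharacterVector cn(canon_codes.size());
  const char *bases = "ACGT";
  for (size_t j = 0; j < canon_codes.size(); ++j) {
    std::string km(k, 'A');
    uint64_t code = canon_codes[j];
    for (int i = k - 1; i >= 0; --i) { km[i] = bases[code & 3]; code >>= 2; }
    cn[j] = km;
  }
  colnames(out) = cn;
  return out;
}

// Second-order Markov sequence; init: 16 probs over the first dinucleotide,
// trans: 16x4 row-stochastic matrix P(next | previous dinucleotide).
// Uses R's RNG so set.seed() governs determinism.
// [[Rcpp::export(name = ".markov_sequence")]]
CharacterVector markov_sequence(int n, NumericVector init, NumericMatrix trans) {
  if (n < 2) stop("n must be >= 2");
  if (init.size() != 16 || trans.nrow() != 16 || trans.ncol() != 4)
    stop("init must have 16 entries and trans must be 16x4");
  std::string s(n, 'A');
  const char *bases = "ACGT";
  RNGScope scope;
  double u = unif_rand(), acc = 0;
  int di = 15;
  for (int i = 0; i < 16; ++i) { acc += init[i]; if (u <= acc) { di = i; break; } }
  s[0] = bases[di >> 2];
  s[1] = bases[di & 3];
  for (int i = 2; i < n; ++i) {
    u = unif_rand(); acc = 0;
    int nb = 3;
    for (int b = 0; b < 4; ++b) { acc += trans(di, b); if (u <= acc) { nb = b; break; } }
    s[i] = bases[nb];
    di = ((di & 3) << 2) | nb;
  }
  return CharacterVector::create(s);
}

// Per-base substitution errors at rate `rate` (uniform over the 3 other
// bases); uses R's RNG.
// [[Rcpp::export(name = ".mutate_seqs")]]
CharacterVector mutate_seqs(CharacterVector seqs, double rate) {
  if (rate < 0 || rate > 1) stop("rate must be in [0,1]");
  CharacterVector out(seqs.size());
  const char *bases = "ACGT";
  RNGScope scope;
  for (int q = 0; q < seqs.size(); ++q) {
    std::string s(CHAR(STRING_ELT(seqs, q)), LENGTH(STRING_ELT(seqs, q)));
    if (rate > 0) {
      for (size_t i = 0; i < s.size(); ++i) {
        if (unif_rand() < rate) {
          int c = base2code(s[i]);
          if (c < 0) continue;
          int nb = (c + 1 + (int)(unif_rand() * 3)) & 3;
          s[i] = bases[nb];
        }
      }
    }
    out[q] = s;
  }
  return out;
}

// Sliding-window quality trim from both ends (Phred+33). Returns 1-based
// [start, end] of the retained segment per read; start > end means the whole
// read is discarded. A window shorter than `window` at the boundary is
// evaluated at its actual size.
// [[Rcpp::export(name = ".sliding_trim")]]
IntegerMatrix sliding_trim(CharacterVector quals, int window, double min_qual) {
  if (window < 1) stop("window must be >= 1");
  IntegerMatrix out(quals.size(), 2);
  for (int q = 0; q < quals.size(); ++q) {
    const char *s = CHAR(STRING_ELT(quals, q));
    int len = LENGTH(STRING_ELT(quals, q));
    int start = 0, end = len;
    while (start < end) {
      int w = std::min(window, end - start);
      double sum = 0;
      for (int i = 0; i < w; ++i) sum += s[start + i] - 33;
      if (sum / w >= min_qual) break;
      ++start;
    }
    while (end > start) {
      int w = std::min(window, end - start);
      double sum = 0;
      for (int i = 0; i < w; ++i) sum += s[end - 1 - i] - 33;
      if (sum / w >= min_qual) break;
      --end;
    }
    out(q, 0) = start + 1;
    out(q, 1) = end;
  }
  return out;
}
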