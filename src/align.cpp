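#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <unordered_set>
using namespace Rcpp;

// Pairwise DNA alignment primitives used by clustering, masking,
// catalog identity and monomer harvesting. Linear gap penalty; scores are
// deliberately simple (match/mismatch/gap) because identity filtering is
// applied downstream on the traceback counts, not on the raw score.

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline bool is_transition(int x, int y) {
  // A<->G (0,2) and C<->T (1,3)
  return (x + y == 2 && x != y) || (x + y == 4 && x != y && x != 2 && y != 2);
}

struct AlnStats {
  int matches = 0, transitions = 0, transversions = 0, n_pairs = 0, alen = 0;
};

static void count_column(int x, int y, AlnStats &st) {
  st.alen++;
  if (x < 0 || y < 0) return; // gap column
  st.n_pairs++;
  if (x == y) st.matches++;
  else if (is_transition(x, y)) st.transitions++;
  else st.transversions++;
}

static List build_result(int score,
                         std::vector<int> &apos, std::vector<int> &bpos,
                         const std::vector<int> &ac, const std::vector<int> &bc,
                         bool keep_path) {
  // apos/bpos collected in reverse during traceback; 0 marks a gap
  std::reverse(apos.begin(), apos.end());
  std::reverse(bpos.begin(), bpos.end());
  AlnStats st;
  for (size_t k = 0; k < apos.size(); ++k) {
    int x = apos[k] > 0 ? ac[apos[k] - 1] : -1;
    int y = bpos[k] > 0 ? bc[bpos[k] - 1] : -1;
    count_column(x, y, st);
  }
  int a_start = 0, a_end = 0, b_start = 0, b_end = 0;
  for (size_t k = 0; k < apos.size(); ++k) {
    if (apos[k] > 0) { if (!a_start) a_start = apos[k]; a_end = apos[k]; }
    if (bpos[k] > 0) { if (!b_start) b_start = bpos[k]; b_end = bpos[k]; }
  }
  List out = List::create(
    _["score"] = score,
    _["a_start"] = a_start, _["a_end"] = a_end,
    _["b_start"] = b_start, _["b_end"] = b_end,
    _["matches"] = st.matches,
    _["transitions"] = st.transitions,
    _["transversions"] = st.transversions,
    _["n_pairs"] = st.n_pairs,
    _["alen"] = st.alen);
  if (keep_path) {
    out["a_pos"] = IntegerVector(apos.begin(), apos.end());
    out["b_pos"] = IntegerVector(bpos.begin(), bpos.end());
  }
  return out;
}

static std::vector<int> encode(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

// Local (Smith-Waterman) alignment of a against b.
// [[Rcpp::export]]
List cpp_align_local(std::string a, std::string b,
                     int match = 1, int mismatch = -2, int gap = -3,
                     bool keep_path = false) {
  const std::vector<int> ac = encode(a), bc = encode(b);
  const int n = (int)ac.size(), m = (int)bc.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  // direction: 0 stop, 1 diag, 2 up (gap in b), 3 left (gap in a)
  std::vector<unsigned char> dir((size_t)(n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      int s = (ac[i - 1] >= 0 && ac[i - 1] == bc[j - 1]) ? match : mismatch;
      int d = prev[j - 1] + s;
      int u = prev[j] + gap;
      int l = cur[j - 1] + gap;
      int v = d; unsigned char dd = 1;
      if (u > v) { v = u; dd = 2; }
      if (l > v) { v = l; dd = 3; }
      if (v <= 0) { v = 0; dd = 0; }
      cur[j] = v;
      dir[(size_t)i * (m + 1) + j] = dd;
      if (v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  std::vector<int> apos, bpos;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    unsigned char d = dir[(size_t)i * (m + 1) + j];
    if (d == 0) break;
    if (d == 1) { apos.push_back(i); bpos.push_back(j); --i; --j; }
    else if (d == 2) { apos.push_back(i); bpos.push_back(0); --i; }
    else { apos.push_back(0); bpos.push_back(j); --j; }
  }
  return build_result(best, apos, bpos, ac, bc, keep_path);
}

// Fit ("glocal") alignment: all of a, free end gaps in b. Used for circular
// identity (a fitted into a doubled partner) and star-alignment projection.
// [[Rcpp::export]]
List cpp_align_fit(std::string a, std::string b,
                   int match = 1, int mismatch = -2, int gap = -3,
                   bool keep_path = false) {
  const std::vector<int> ac = encode(a), bc = encode(b);
  const int n = (int)ac.size(), m = (int)bc.size();
  const int NEG = -1000000000;
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> dir((size_t)(n + 1) * (m + 1), 0);
  for (int j = 0; j <= m; ++j) prev[j] = 0; // free b prefix
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    dir[(size_t)i * (m + 1)] = 2;
    for (int j = 1; j <= m; ++j) {
      int s = (ac[i - 1] >= 0 && ac[i - 1] == bc[j - 1]) ? match : mismatch;
      int d = (prev[j - 1] <= NEG ? NEG : prev[j - 1] + s);
      int u = (prev[j] <= NEG ? NEG : prev[j] + gap);
      int l = (cur[j - 1] <= NEG ? NEG : cur[j - 1] + gap);
      int v = d; unsigned char dd = 1;
      if (u > v) { v = u; dd = 2; }
      if (l > v) { v = l; dd = 3; }
      cur[j] = v;
      dir[(size_t)i * (m + 1) + j] = dd;
    }
    std::swap(prev, cur);
  }
  // best over last row (free b suffix)
  int best = prev[0], bj = 0;
  for (int j = 1; j <= m; ++j) if (prev[j] > best) { best = prev[j]; bj = j; }
  std::vector<int> apos, bpos;
  int i = n, j = bj;
  while (i > 0) {
    unsigned char d = dir[(size_t)i * (m + 1) + j];
    if (d == 1) { apos.push_back(i); bpos.push_back(j); --i; --j; }
    else if (d == 2) { apos.push_back(i); bpos.push_back(0); --i; }
    else { apos.push_back(0); bpos.push_back(j); --j; }
  }
  return build_result(best, apos, bpos, ac, bc, keep_path);
}

// Circular, strand-aware identity: for every rotation of b (both strands)
// align a globally with free end gaps in the rotated partner; identity =
// matches / (alignment columns + uncovered partner length), reported for
// the best-scoring alignment (ties resolved toward higher identity).
// Exact but O(len_a * len_b^2); intended for monomer-scale sequences.
// [[Rcpp::export]]
double cpp_rotation_identity(std::string a, std::string b,
                             int match = 1, int mismatch = -2,
                             int gap = -3) {
  if (a.size() > b.size()) std::swap(a, b);
  const std::vector<int> ac = encode(a);
  const int n = (int)ac.size();
  std::string brc(b.rbegin(), b.rend());
  for (auto &c : brc) {
    int v = base_code(c);
    c = (v >= 0) ? "TGCA"[v] : 'N';
  }
  const int m = (int)b.size();
  int best_score = INT_MIN;
  double best_id = 0.0;
  std::vector<int> S((n + 1) * (m + 1)), M((n + 1) * (m + 1)),
      L((n + 1) * (m + 1)), B((n + 1) * (m + 1));
  for (const std::string &strand : {b, brc}) {
    for (int r = 0; r < m; ++r) {
      std::string rot = strand.substr(r) + strand.substr(0, r);
      const std::vector<int> bc = encode(rot);
      auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
      for (int j = 0; j <= m; ++j) {
        S[idx(0, j)] = 0; M[idx(0, j)] = 0; L[idx(0, j)] = 0;
        B[idx(0, j)] = 0;
      }
      for (int i = 1; i <= n; ++i) {
        S[idx(i, 0)] = i * gap; M[idx(i, 0)] = 0; L[idx(i, 0)] = i;
        B[idx(i, 0)] = 0;
        for (int j = 1; j <= m; ++j) {
          bool mt = ac[i - 1] >= 0 && ac[i - 1] == bc[j - 1];
          int d = S[idx(i - 1, j - 1)] + (mt ? match : mismatch);
          int u = S[idx(i - 1, j)] + gap;
          int l = S[idx(i, j - 1)] + gap;
          if (d >= u && d >= l) {
            S[idx(i, j)] = d;
            M[idx(i, j)] = M[idx(i - 1, j - 1)] + (mt ? 1 : 0);
            L[idx(i, j)] = L[idx(i - 1, j - 1)] + 1;
            B[idx(i, j)] = B[idx(i - 1, j - 1)] + 1;
          } else if (u >= l) {
            S[idx(i, j)] = u;
            M[idx(i, j)] = M[idx(i - 1, j)];
            L[idx(i, j)] = L[idx(i - 1, j)] + 1;
            B[idx(i, j)] = B[idx(i - 1, j)];
          } else {
            S[idx(i, j)] = l;
            M[idx(i, j)] = M[idx(i, j - 1)];
            L[idx(i, j)] = L[idx(i, j - 1)] + 1;
            B[idx(i, j)] = B[idx(i, j - 1)] + 1;
          }
        }
      }
      for (int j = 0; j <= m; ++j) {
        int len = L[idx(n, j)] + (m - B[idx(n, j)]);
        if (len == 0) continue;
        double id = (double)M[idx(n, j)] / len;
        if (S[idx(n, j)] > best_score ||
            (S[idx(n, j)] == best_score && id > best_id)) {
          best_score = S[idx(n, j)];
          best_id = id;
        }
      }
    }
  }
  return best_id > 1.0 ? 1.0 : best_id;
}

static inline uint32_t revcomp_code(uint32_t code, int k) {
  uint32_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3u - (code & 3u));
    code >>= 2;
  }
  return rc;
}

// Sorted unique canonical k-mer codes per sequence (k <= 15; non-ACGT
// positions break k-mers). Canonical = min(code, revcomp(code)) so that
// downstream comparisons are strand-symmetric.
// [[Rcpp::export]]
List cpp_kmer_sets(CharacterVector seqs, int k) {
  if (k < 1 || k > 15) stop("k must be in 1..15");
  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  List out(seqs.size());
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string str = as<std::string>(seqs[s]);
    std::vector<uint32_t> km;
    uint32_t code = 0; int run = 0;
    for (size_t i = 0; i < str.size(); ++i) {
      int c = base_code(str[i]);
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)c) & mask;
      if (++run >= k) km.push_back(std::min(code, revcomp_code(code, k)));
    }
    std::sort(km.begin(), km.end());
    km.erase(std::unique(km.begin(), km.end()), km.end());
    IntegerVector iv(km.size());
    for (size_t i = 0; i < km.size(); ++i) iv[i] = (int)km[i];
    out[s] = iv;
  }
  return out;
}

// For each sequence, count of distinct canonical k-mers shared with each
// reference k-mer set (columns). Cheap prescreen before alignment.
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_match(CharacterVector seqs, int k, List ref_sets) {
  List q = cpp_kmer_sets(seqs, k);
  const int nref = ref_sets.size();
  std::vector<std::unordered_set<int> > refs(nref);
  for (int r = 0; r < nref; ++r) {
    IntegerVector rv = ref_sets[r];
    refs[r].insert(rv.begin(), rv.end());
  }
  IntegerMatrix out(seqs.size(), nref);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    IntegerVector qs = q[s];
    for (int r = 0; r < nref; ++r) {
      int cnt = 0;
      for (int v : qs) if (refs[r].count(v)) ++cnt;
      out(s, r) = cnt;
    }
  }
  return out;
}
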