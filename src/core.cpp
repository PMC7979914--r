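#include <Rcpp.h>
using namespace Rcpp;

// Hamming distance between two equal-length strings. Unequal lengths are a
// caller error and are checked on the R side; here we guard anyway.
// [[Rcpp::export]]
int hamming_cpp(const std::string& a, const std::string& b) {
  if (a.size() != b.size()) stop("hamming_cpp: unequal lengths");
  int d = 0;
  for (size_t k = 0; k < a.size(); ++k) if (a[k] != b[k]) ++d;
  return d;
}

// Mismatch count with early exit once the count exceeds `cap`.
static inline int mismatch_capped(const std::string& a, const std::string& b,
                                  int cap) {
  int d = 0;
  for (size_t k = 0; k < a.size(); ++k) {
    if (a[k] != b[k] && ++d > cap) return d;
  }
  return d;
}

// For each singleton key, locate the abundant key (same length assumed by the
// caller's length bucketing) within Hamming distance <= h that has the highest
// count, ties broken by lexicographically smallest key. Returns 1-based index
// into `abundant`, or NA when no abundant key is within h.
// [[Rcpp::export]]
IntegerVector absorb_singletons_cpp(const CharacterVector& singletons,
                                    const CharacterVector& abundant,
                                    const IntegerVector& abundant_count,
                                    int h) {
  int ns = singletons.size(), na = abundant.size();
  IntegerVector out(ns, NA_INTEGER);
  std::vector<std::string> ab(na);
  for (int j = 0; j < na; ++j) ab[j] = as<std::string>(abundant[j]);
  for (int i = 0; i < ns; ++i) {
    std::string s = as<std::string>(singletons[i]);
    int best = -1;
    for (int j = 0; j < na; ++j) {
      if (ab[j].size() != s.size()) continue;
      if (mismatch_capped(s, ab[j], h) <= h) {
        if (best < 0) { best = j; continue; }
        if (abundant_count[j] > abundant_count[best] ||
            (abundant_count[j] == abundant_count[best] && ab[j] < ab[best]))
          best = j;
      }
    }
    if (best >= 0) out[i] = best + 1;
  }
  return out;
}

// Ungapped alignment of each reference against each read over candidate
// offsets 0..max_shift (reference start relative to read start). The score is
// matches - mismatches over the overlap; the reference must overlap the read
// by at least min_overlap bases. Returns, per (read, ref), the best-scoring
// offset with its mismatch count and overlap length.
// [[Rcpp::export]]
List best_ungapped_cpp(const CharacterVector& reads,
                       const CharacterVector& refs,
                       int max_shift, int min_overlap) {
  int nr = reads.size(), ng = refs.size();
  std::vector<std::string> rf(ng);
  for (int g = 0; g < ng; ++g) rf[g] = as<std::string>(refs[g]);
  IntegerMatrix score(nr, ng), offset(nr, ng), mism(nr, ng), ovl(nr, ng);
  for (int i = 0; i < nr; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int L = rd.size();
    for (int g = 0; g < ng; ++g) {
      const std::string& rr = rf[g];
      int M = rr.size();
      int best_s = INT_MIN, best_o = NA_INTEGER, best_m = NA_INTEGER,
          best_l = NA_INTEGER;
      for (int o = 0; o <= max_shift; ++o) {
        int len = std::min(M, L - o);
        if (len < min_overlap) break;
        int d = 0;
        const char* p = rd.data() + o;
        const char* q = rr.data();
        for (int k = 0; k < len; ++k) if (p[k] != q[k]) ++d;
        int s = len - 2 * d;
        if (s > best_s) { best_s = s; best_o = o; best_m = d; best_l = len; }
      }
      score(i, g) = (best_o == NA_INTEGER) ? NA_INTEGER : best_s;
      offset(i, g) = best_o;
      mism(i, g) = best_m;
      ovl(i, g) = best_l;
    }
  }
  return List::create(_["score"] = score, _["offset"] = offset,
                      _["mismatch"] = mism, _["overlap"] = ovl);
}

// End-anchored alignment for J segments: each reference suffix is slid over
// the 3' end of the read, with the reference end placed `shift` bases before
// the read end, shift = 0..max_shift. Best (fewest-mismatch, then smallest
// shift) placement per (read, ref).
// [[Rcpp::export]]
List align_tail_cpp(const CharacterVector& reads,
                    const CharacterVector& refs,
                    int max_shift) {
  int nr = reads.size(), ng = refs.size();
  std::vector<std::string> rf(ng);
  for (int g = 0; g < ng; ++g) rf[g] = as<std::string>(refs[g]);
  IntegerMatrix mism(nr, ng), start(nr, ng);
  for (int i = 0; i < nr; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int L = rd.size();
    for (int g = 0; g < ng; ++g) {
      const std::string& rr = rf[g];
      int M = rr.size();
      int best_m = NA_INTEGER, best_st = NA_INTEGER;
      for (int sh = 0; sh <= max_shift; ++sh) {
        int st = L - M - sh;
        if (st < 0) break;
        int d = 0;
        const char* p = rd.data() + st;
        for (int k = 0; k < M; ++k) if (p[k] != rr[k]) ++d;
        if (best_m == NA_INTEGER || d < best_m) { best_m = d; best_st = st; }
      }
      mism(i, g) = best_m;
      start(i, g) = (best_st == NA_INTEGER) ? NA_INTEGER : best_st + 1; // 1-based
    }
  }
  return List::create(_["mismatch"] = mism, _["start"] = start);
}

// Full pairwise Levenshtein distance matrix (unit costs) for moderate n;
// used for binder sequence-dissimilarity profiles.
// [[Rcpp::export]]
IntegerMatrix levenshtein_matrix_cpp(const CharacterVector& x) {
  int n = x.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(x[i]);
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const std::string &a = s[i], &b = s[j];
      int la = a.size(), lb = b.size();
      std::vector<int> prev(lb + 1), cur(lb + 1);
      for (int q = 0; q <= lb; ++q) prev[q] = q;
      for (int p = 1; p <= la; ++p) {
        cur[0] = p;
        for (int q = 1; q <= lb; ++q) {
          int sub = prev[q - 1] + (a[p - 1] != b[q - 1]);
          cur[q] = std::min(sub, std::min(prev[q] + 1, cur[q - 1] + 1));
        }
        std::swap(prev, cur);
      }
      out(i, j) = out(j, i) = prev[lb];
    }
  }
  return out;
}
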