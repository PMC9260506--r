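#include <Rcpp.h>
using namespace Rcpp;

// Hamming distance between equal-length strings; -1 if lengths differ.
// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector x, CharacterVector y) {
  R_xlen_t n = x.size();
  if (y.size() != n) stop("x and y must have the same length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(x, i));
    const char *b = CHAR(STRING_ELT(y, i));
    R_xlen_t la = LENGTH(STRING_ELT(x, i)), lb = LENGTH(STRING_ELT(y, i));
    if (la != lb) { out[i] = -1; continue; }
    int d = 0;
    for (R_xlen_t k = 0; k < la; ++k) if (a[k] != b[k]) ++d;
    out[i] = d;
  }
  return out;
}

// All-pairs Hamming distances among equal-length strings (dense matrix).
// [[Rcpp::export]]
IntegerMatrix cpp_hamming_matrix(CharacterVector x) {
  int n = x.size();
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(x, i));
    int la = LENGTH(STRING_ELT(x, i));
    for (int j = i + 1; j < n; ++j) {
      const char *b = CHAR(STRING_ELT(x, j));
      int d;
      if (LENGTH(STRING_ELT(x, j)) != la) d = -1;
      else { d = 0; for (int k = 0; k < la; ++k) if (a[k] != b[k]) ++d; }
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}

// Overlap-merge one read pair. r2rc is the reverse complement of the raw R2
// (i.e. in R1 orientation); q1/q2rc are Phred+33 strings matching r1/r2rc, or
// empty strings when qualities are unavailable. Candidate configurations
// overlap the suffix of r1 with the prefix of r2rc by L bases,
// min_overlap <= L <= min(n1, n2); the merged read has length n1 + n2 - L.
// The best configuration maximises the number of matching overlap bases among
// those with mismatch fraction <= max_mismatch_frac; an exact tie in matches
// between two configurations is reported as "ambiguous". Disagreeing overlap
// bases take the higher-quality base, ties going to r1.
// [[Rcpp::export]]
List cpp_merge_pair(std::string r1, std::string r2rc,
                    std::string q1, std::string q2rc,
                    int min_overlap, double max_mismatch_frac) {
  int n1 = r1.size(), n2 = r2rc.size();
  int lmax = std::min(n1, n2);
  if (min_overlap < 1) min_overlap = 1;
  if (lmax < min_overlap)
    return List::create(_["merged"] = CharacterVector::create(NA_STRING),
                        _["status"] = "no_overlap",
                        _["overlap"] = NA_INTEGER);
  int best_matches = -1, best_L = -1;
  bool tie = false;
  for (int L = min_overlap; L <= lmax; ++L) {
    int m = 0;
    const char *a = r1.c_str() + (n1 - L);
    const char *b = r2rc.c_str();
    for (int k = 0; k < L; ++k) if (a[k] == b[k]) ++m;
    double mmfrac = (double)(L - m) / (double)L;
    if (mmfrac > max_mismatch_frac) continue;
    if (m > best_matches) { best_matches = m; best_L = L; tie = false; }
    else if (m == best_matches) tie = true;
  }
  if (best_matches < 0)
    return List::create(_["merged"] = CharacterVector::create(NA_STRING),
                        _["status"] = "no_overlap",
                        _["overlap"] = NA_INTEGER);
  if (tie)
    return List::create(_["merged"] = CharacterVector::create(NA_STRING),
                        _["status"] = "ambiguous",
                        _["overlap"] = NA_INTEGER);
  int L = best_L;
  bool have_q = (int)q1.size() == n1 && (int)q2rc.size() == n2;
  std::string merged;
  merged.reserve(n1 + n2 - L);
  merged.append(r1, 0, n1 - L);
  for (int k = 0; k < L; ++k) {
    char c1 = r1[n1 - L + k], c2 = r2rc[k];
    if (c1 == c2) { merged.push_back(c1); continue; }
    if (have_q && q2rc[k] > q1[n1 - L + k]) merged.push_back(c2);
    else merged.push_back(c1);
  }
  merged.append(r2rc, L, n2 - L);
  return List::create(_["merged"] = merged, _["status"] = "merged",
                      _["overlap"] = L);
}

// Best Hamming-match offset of a short anchor inside a read. Returns the
// 1-based start of the unique best match if its distance <= max_mm, else 0
// (absent) or -1 (ambiguous best).
// [[Rcpp::export]]
int cpp_find_anchor(std::string read, std::string anchor, int max_mm) {
  int n = read.size(), m = anchor.size();
  if (m == 0 || m > n) return 0;
  int best = m + 1, best_pos = 0;
  bool tie = false;
  for (int s = 0; s + m <= n; ++s) {
    int d = 0;
    for (int k = 0; k < m && d < best + 1; ++k)
      if (read[s + k] != anchor[k]) ++d;
    if (d < best) { best = d; best_pos = s + 1; tie = false; }
    else if (d == best) tie = true;
  }
  if (best > max_mm) return 0;
  if (tie) return -1;
  return best_pos;
}
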