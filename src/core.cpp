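#include <Rcpp.h>
#include <string>
#include <vector>
#include <array>
#include <unordered_set>
#include <algorithm>
#include <climits>
#include <cmath>
using namespace Rcpp;

// Matched positions on an optimal-score global alignment with affine gaps
// (Gotoh).  Scoring (doubled integer units): match +2, mismatch -3, gap
// run of length g costs -(16 + 2g).  Affine gaps keep alignments compact, so
// the identity of sequences of very different lengths reflects their best
// contiguous agreement rather than scattered single-residue matches.
// Among equal-score alignments the one with most matches is taken.
//
// Implementation notes: score and match count are packed into one integer
// (v = score * 4096 + matches, 0 <= matches < 4096) so the lexicographic
// maximum is a plain integer maximum, and the DP is banded around the
// length-difference diagonal (margin 16) — with these gap costs, excursions
// beyond the band cost more than the matches they could recover.
static int nw_matches(const std::string &a, const std::string &b) {
  const int SH = 4096;
  const int MAT = 2 * SH + 1, MIS = -3 * SH, OPENEXT = 18 * SH,
      EXT = 2 * SH;
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return 0;
  if (n >= SH || m >= SH) Rcpp::stop("sequences longer than 4095 unsupported");
  const int NEG = -500000000;
  const int W = 16;
  const int dlo = std::min(0, m - n) - W;   // allowed offsets d = j - i
  const int dhi = std::max(0, m - n) + W;
  std::vector<int> M(m + 1, NEG), X(m + 1, NEG), Y(m + 1, NEG),
      pM(m + 1, NEG), pX(m + 1, NEG), pY(m + 1, NEG);
  pM[0] = 0;
  for (int j = 1; j <= m; ++j) {
    if (j <= dhi) pY[j] = -(16 * SH + 2 * SH * j);
  }
  for (int i = 1; i <= n; ++i) {
    const int jlo = std::max(1, i + dlo), jhi = std::min(m, i + dhi);
    M[0] = NEG; Y[0] = NEG;
    X[0] = (-i >= dlo) ? -(16 * SH + 2 * SH * i) : NEG;
    if (jlo > 1) { M[jlo - 1] = NEG; X[jlo - 1] = NEG; Y[jlo - 1] = NEG; }
    const char ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      int diag = std::max(pM[j - 1], std::max(pX[j - 1], pY[j - 1]));
      M[j] = (diag <= NEG) ? NEG : diag + (ai == b[j - 1] ? MAT : MIS);
      int up = std::max(pM[j] - OPENEXT,
                        std::max(pX[j] - EXT, pY[j] - OPENEXT));
      X[j] = (up < NEG) ? NEG : up;
      int left = std::max(M[j - 1] - OPENEXT,
                          std::max(Y[j - 1] - EXT, X[j - 1] - OPENEXT));
      Y[j] = (left < NEG) ? NEG : left;
    }
    if (jhi < m) { M[jhi + 1] = NEG; X[jhi + 1] = NEG; Y[jhi + 1] = NEG; }
    std::swap(M, pM); std::swap(X, pX); std::swap(Y, pY);
  }
  const int v = std::max(pM[m], std::max(pX[m], pY[m]));
  return ((v % SH) + SH) % SH;
}

static void count_residues(const std::string &s, int *cnt) {
  for (int i = 0; i < 26; ++i) cnt[i] = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    const int c = s[i] - 'A';
    if (c >= 0 && c < 26) cnt[c]++;
  }
}

static double pair_identity(const std::string &a, const std::string &b) {
  const int shorter = (int)std::min(a.size(), b.size());
  if (shorter == 0) return 0.0;
  return (double)nw_matches(a, b) / shorter;
}

// [[Rcpp::export]]
NumericVector nw_identity_cpp(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("a and b must have equal length");
  NumericVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    out[i] = pair_identity(as<std::string>(a[i]), as<std::string>(b[i]));
  }
  return out;
}

// Minimum evidence for a cluster join: besides identity >= threshold, at
// least min(8, shorter) positions must match, so chance agreement between
// short unrelated peptides does not merge them (heuristic word-filtered
// clustering tools behave the same way in practice).
static inline int min_matches_required(double threshold, int shorter) {
  const int evid = shorter < 8 ? shorter : 8;
  const int byid = (int)std::ceil(threshold * shorter - 1e-9);
  return byid > evid ? byid : evid;
}

// Greedy longest-first clustering.  `seqs` must already be sorted by
// decreasing length; returns, for each sequence, the 1-based index of its
// cluster representative (itself if it founds a cluster).  A residue-count
// intersection bound (matches can never exceed sum_a min(n_a, m_a)) prunes
// alignments that cannot reach the threshold.
// [[Rcpp::export]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, double threshold) {
  const int n = seqs.size();
  IntegerVector rep(n);
  std::vector<std::string> ss(n);
  std::vector<std::array<int, 26>> cnts(n);
  for (int i = 0; i < n; ++i) {
    ss[i] = as<std::string>(seqs[i]);
    count_residues(ss[i], cnts[i].data());
  }
  std::vector<int> reps;
  reps.reserve(n);
  for (int i = 0; i < n; ++i) {
    int found = 0;
    const int li = (int)ss[i].size();
    for (size_t r = 0; r < reps.size(); ++r) {
      const int j = reps[r];
      const int shorter = std::min(li, (int)ss[j].size());
      if (shorter == 0) continue;
      const int need = min_matches_required(threshold, shorter);
      int bound = 0;
      for (int c = 0; c < 26; ++c) bound += std::min(cnts[i][c], cnts[j][c]);
      if (bound < need) continue;
      if (nw_matches(ss[i], ss[j]) >= need) {
        found = j + 1;
        break;
      }
    }
    if (found) rep[i] = found;
    else { reps.push_back(i); rep[i] = i + 1; }
  }
  return rep;
}

// TRUE where candidate i has identity >= threshold with at least one
// member of `set` (same pruning as greedy_cluster_cpp).
// [[Rcpp::export]]
LogicalVector identity_vs_set_cpp(CharacterVector cand, CharacterVector set,
                                  double threshold) {
  const int n = cand.size(), k = set.size();
  std::vector<std::string> ss(k);
  std::vector<std::array<int, 26>> cnts(k);
  for (int j = 0; j < k; ++j) {
    ss[j] = as<std::string>(set[j]);
    count_residues(ss[j], cnts[j].data());
  }
  LogicalVector out(n);
  std::array<int, 26> ci;
  for (int i = 0; i < n; ++i) {
    const std::string s = as<std::string>(cand[i]);
    count_residues(s, ci.data());
    bool hit = false;
    for (int j = 0; j < k && !hit; ++j) {
      const int shorter = (int)std::min(s.size(), ss[j].size());
      if (shorter == 0) continue;
      const int need = min_matches_required(threshold, shorter);
      int bound = 0;
      for (int c = 0; c < 26; ++c) bound += std::min(ci[c], cnts[j][c]);
      if (bound < need) continue;
      hit = nw_matches(s, ss[j]) >= need;
    }
    out[i] = hit;
  }
  return out;
}

// LZ76 exhaustive-history phrase count (Kaspar & Schuster formulation).
static int lz76_one(const std::string &s) {
  const int n = (int)s.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// [[Rcpp::export]]
IntegerVector lz76_cpp(CharacterVector xs) {
  IntegerVector out(xs.size());
  for (R_xlen_t i = 0; i < xs.size(); ++i)
    out[i] = lz76_one(as<std::string>(xs[i]));
  return out;
}

// Similarity profile: s(x, r) = 1 - (C(x.r) - min(Cx, Cr)) / max(Cx, Cr),
// C = LZ76 phrase count, "." concatenation.  Rows = xs, columns = refs.
// [[Rcpp::export]]
NumericMatrix lz_profile_cpp(CharacterVector xs, CharacterVector refs) {
  const int nx = xs.size(), nr = refs.size();
  std::vector<std::string> rs(nr);
  std::vector<int> cr(nr);
  for (int j = 0; j < nr; ++j) {
    rs[j] = as<std::string>(refs[j]);
    cr[j] = lz76_one(rs[j]);
  }
  NumericMatrix out(nx, nr);
  std::string cat;
  for (int i = 0; i < nx; ++i) {
    const std::string x = as<std::string>(xs[i]);
    const int cx = lz76_one(x);
    for (int j = 0; j < nr; ++j) {
      cat = x + rs[j];
      const int cxr = lz76_one(cat);
      const int lo = std::min(cx, cr[j]), hi = std::max(cx, cr[j]);
      out(i, j) = hi == 0 ? 1.0 : 1.0 - (double)(cxr - lo) / hi;
    }
  }
  return out;
}

// Does each candidate share a contiguous k-mer with any positive sequence?
// [[Rcpp::export]]
LogicalVector shares_kmer_cpp(CharacterVector cand, CharacterVector pos,
                              int k) {
  std::unordered_set<std::string> bank;
  for (R_xlen_t i = 0; i < pos.size(); ++i) {
    const std::string p = as<std::string>(pos[i]);
    if ((int)p.size() < k) continue;
    for (size_t j = 0; j + k <= p.size(); ++j) bank.insert(p.substr(j, k));
  }
  LogicalVector out(cand.size());
  for (R_xlen_t i = 0; i < cand.size(); ++i) {
    const std::string s = as<std::string>(cand[i]);
    bool hit = false;
    if ((int)s.size() >= k) {
      for (size_t j = 0; j + k <= s.size() && !hit; ++j)
        hit = bank.count(s.substr(j, k)) > 0;
    }
    out[i] = hit;
  }
  return out;
}

// Distinct n-grams of one sequence: contiguous 1-/2-/3-grams plus 2-grams
// with a single gap (X_Y) and 3-grams with a single internal gap
// (XY_Z, X_YZ).  "_" marks the gapped position.
static void ngrams_of(const std::string &s,
                      std::unordered_set<std::string> &out) {
  const int n = (int)s.size();
  for (int i = 0; i < n; ++i) {
    out.insert(s.substr(i, 1));
    if (i + 1 < n) out.insert(s.substr(i, 2));
    if (i + 2 < n) {
      out.insert(s.substr(i, 3));
      std::string g2 = "X_Y";
      g2[0] = s[i]; g2[2] = s[i + 2];
      out.insert(g2);
    }
    if (i + 3 < n) {
      std::string a = "XY_Z", b = "X_YZ";
      a[0] = s[i]; a[1] = s[i + 1]; a[3] = s[i + 3];
      b[0] = s[i]; b[2] = s[i + 2]; b[3] = s[i + 3];
      out.insert(a);
      out.insert(b);
    }
  }
}

// CTD distribution descriptors for many peptides at once.  `class_map` is
// a 7 x 20 integer matrix assigning each residue code (1..20) to a class
// (1..3) per attribute; `codes` maps characters to residue codes.
// Descriptors per attribute/class: relative positions of the first
// occurrence and of the 25/50/75/100% quantile occurrences; absent
// classes give zeros.  Must agree exactly with the R reference
// implementation ctd_distribution().
// [[Rcpp::export]]
NumericMatrix ctd_matrix_cpp(CharacterVector seqs, IntegerMatrix class_map,
                             IntegerVector codes) {
  const int n = seqs.size(), n_attr = class_map.nrow();
  NumericMatrix out(n, n_attr * 15);
  std::vector<int> pos[3];
  for (int i = 0; i < n; ++i) {
    const std::string s = as<std::string>(seqs[i]);
    const int L = (int)s.size();
    for (int a = 0; a < n_attr; ++a) {
      for (int g = 0; g < 3; ++g) pos[g].clear();
      for (int p = 0; p < L; ++p) {
        const int code = codes[(unsigned char)s[p]];
        if (code < 1) stop("non-standard residue");
        const int cls = class_map(a, code - 1);
        pos[cls - 1].push_back(p + 1);
      }
      for (int g = 0; g < 3; ++g) {
        const int base = a * 15 + g * 5;
        const int k = (int)pos[g].size();
        if (k == 0) continue;
        const double qs[5] = {0, 0.25, 0.5, 0.75, 1};
        for (int q = 0; q < 5; ++q) {
          int at = (int)std::ceil(qs[q] * k);
          if (at < 1) at = 1;
          out(i, base + q) = (double)pos[g][at - 1] / L;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List ngram_sets_cpp(CharacterVector seqs) {
  List out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::unordered_set<std::string> set;
    ngrams_of(as<std::string>(seqs[i]), set);
    CharacterVector v(set.size());
    int j = 0;
    for (const auto &g : set) v[j++] = g;
    out[i] = v;
  }
  return out;
}
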