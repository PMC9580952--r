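#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

// Needleman-Wunsch global alignment, linear gap penalty.
// Scoring pinned for determinism: match +1, mismatch -1, gap -2.
// Traceback ties prefer substitution (diagonal) over a gap, then a gap in
// the second sequence over a gap in the first; operands are ordered
// canonically first so the tie rule cannot break symmetry.
// Identity = matching columns / alignment columns excluding terminal gaps.
// 'N' never counts as a match, not even against another 'N'.
static double nw_identity_ordered(const char *a, int n, const char *b, int m) {
  const int MATCH = 1, MIS = -1, GAP = -2;
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = GAP * j; tb[j] = 2; }
  tb[0] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = GAP * i;
    tb[(size_t)i * (m + 1)] = 1;
    const char ai = a[i - 1];
    unsigned char *tbrow = &tb[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      int sub  = prev[j - 1] + ((ai == b[j - 1] && ai != 'N') ? MATCH : MIS);
      int up   = prev[j] + GAP;     // gap in b, consumes a
      int left = cur[j - 1] + GAP;  // gap in a, consumes b
      int best = sub; unsigned char dir = 0;
      if (up > best)   { best = up;   dir = 1; }
      if (left > best) { best = left; dir = 2; }
      cur[j] = best;
      tbrow[j] = dir;
    }
    std::swap(prev, cur);
  }
  // Traceback; column types: 0 = gap, 1 = match, 2 = mismatch.
  std::vector<unsigned char> colt;
  colt.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char dir;
    if (i == 0) dir = 2;
    else if (j == 0) dir = 1;
    else dir = tb[(size_t)i * (m + 1) + j];
    if (dir == 0) {
      colt.push_back((a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? 1 : 2);
      --i; --j;
    } else if (dir == 1) {
      colt.push_back(0); --i;
    } else {
      colt.push_back(0); --j;
    }
  }
  int L = (int)colt.size();
  int s = 0, e = L - 1;
  while (s <= e && colt[s] == 0) ++s;  // terminal gap run (one end)
  while (e >= s && colt[e] == 0) --e;  // terminal gap run (other end)
  int denom = 0, matches = 0;
  for (int k = s; k <= e; ++k) {
    ++denom;
    if (colt[k] == 1) ++matches;
  }
  if (denom == 0) return 0.0;
  return (double)matches / (double)denom;
}

// Canonical orientation: shorter sequence (then lexicographically smaller)
// goes first, so identity(a, b) == identity(b, a) exactly.
static double nw_identity_impl(const char *a, int n, const char *b, int m) {
  bool swap = false;
  if (n != m) swap = n > m;
  else {
    int c = std::memcmp(a, b, (size_t)n);
    swap = c > 0;
  }
  if (swap) return nw_identity_ordered(b, m, a, n);
  return nw_identity_ordered(a, n, b, m);
}

// [[Rcpp::export]]
double nw_identity_cpp(const std::string &a, const std::string &b) {
  if (a.empty() || b.empty())
    stop("sequences must be non-empty");
  return nw_identity_impl(a.c_str(), (int)a.size(), b.c_str(), (int)b.size());
}

// [[Rcpp::export]]
NumericVector nw_identity_many_cpp(const std::string &query, CharacterVector refs) {
  if (query.empty()) stop("query sequence must be non-empty");
  int n = refs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(refs[i]);
    if (r.empty()) stop("reference sequence must be non-empty");
    out[i] = nw_identity_impl(query.c_str(), (int)query.size(),
                              r.c_str(), (int)r.size());
  }
  return out;
}

// Exhaustive Hamming-identity audit over equal-length ungapped sequences,
// stratified by planted lineage tier. Rows: same species / same genus,
// different species / same family, different genus / different family.
// Columns: min identity, max identity, number of pairs.
// [[Rcpp::export]]
NumericMatrix tier_identity_range_cpp(CharacterVector seqs, IntegerVector fam,
                                      IntegerVector gen, IntegerVector sp) {
  int n = seqs.size();
  if (fam.size() != n || gen.size() != n || sp.size() != n)
    stop("group index vectors must match the number of sequences");
  std::vector<std::string> ss(n);
  int L = -1;
  for (int i = 0; i < n; ++i) {
    ss[i] = as<std::string>(seqs[i]);
    if (L < 0) L = (int)ss[i].size();
    else if ((int)ss[i].size() != L) stop("sequences must have equal length");
  }
  NumericMatrix out(4, 3);
  for (int t = 0; t < 4; ++t) { out(t, 0) = 1.0; out(t, 1) = 0.0; out(t, 2) = 0.0; }
  for (int i = 0; i < n; ++i) {
    const char *si = ss[i].c_str();
    for (int j = i + 1; j < n; ++j) {
      const char *sj = ss[j].c_str();
      int d = 0;
      for (int k = 0; k < L; ++k) if (si[k] != sj[k]) ++d;
      double id = 1.0 - (double)d / (double)L;
      int t;
      if (fam[i] != fam[j]) t = 3;
      else if (gen[i] != gen[j]) t = 2;
      else if (sp[i] != sp[j]) t = 1;
      else t = 0;
      if (id < out(t, 0)) out(t, 0) = id;
      if (id > out(t, 1)) out(t, 1) = id;
      out(t, 2) += 1.0;
    }
  }
  for (int t = 0; t < 4; ++t) if (out(t, 2) == 0.0) { out(t, 0) = NA_REAL; out(t, 1) = NA_REAL; }
  return out;
}

// Extreme pairs per tier under Hamming identity: the k highest-identity
// pairs for the three cross-clade tiers (where the band's upper edge
// matters) and the k lowest-identity pairs for the within-species tier
// (lower edge matters). Used to re-verify the guard bands under the full
// alignment identity, which can only plausibly differ on these extremes.
// Columns: tier (0..3), i, j (1-based), hamming identity.
// [[Rcpp::export]]
NumericMatrix tier_extreme_pairs_cpp(CharacterVector seqs, IntegerVector fam,
                                     IntegerVector gen, IntegerVector sp,
                                     int k) {
  int n = seqs.size();
  std::vector<std::string> ss(n);
  int L = -1;
  for (int i = 0; i < n; ++i) {
    ss[i] = as<std::string>(seqs[i]);
    if (L < 0) L = (int)ss[i].size();
    else if ((int)ss[i].size() != L) stop("sequences must have equal length");
  }
  struct Rec { double id; int i, j; };
  std::vector<std::vector<Rec> > keep(4);
  for (int i = 0; i < n; ++i) {
    const char *si = ss[i].c_str();
    for (int j = i + 1; j < n; ++j) {
      const char *sj = ss[j].c_str();
      int d = 0;
      for (int p = 0; p < L; ++p) if (si[p] != sj[p]) ++d;
      double id = 1.0 - (double)d / (double)L;
      int t;
      if (fam[i] != fam[j]) t = 3;
      else if (gen[i] != gen[j]) t = 2;
      else if (sp[i] != sp[j]) t = 1;
      else t = 0;
      std::vector<Rec> &v = keep[t];
      // tier 0: keep smallest identities; tiers 1-3: keep largest
      bool want = (int)v.size() < k;
      if (!want) {
        if (t == 0) want = id < v.back().id;
        else want = id > v.back().id;
      }
      if (want) {
        Rec r; r.id = id; r.i = i + 1; r.j = j + 1;
        v.push_back(r);
        if (t == 0)
          std::sort(v.begin(), v.end(),
                    [](const Rec &x, const Rec &y) { return x.id < y.id; });
        else
          std::sort(v.begin(), v.end(),
                    [](const Rec &x, const Rec &y) { return x.id > y.id; });
        if ((int)v.size() > k) v.pop_back();
      }
    }
  }
  int total = 0;
  for (int t = 0; t < 4; ++t) total += (int)keep[t].size();
  NumericMatrix out(total, 4);
  int r = 0;
  for (int t = 0; t < 4; ++t)
    for (size_t q = 0; q < keep[t].size(); ++q, ++r) {
      out(r, 0) = t; out(r, 1) = keep[t][q].i; out(r, 2) = keep[t][q].j;
      out(r, 3) = keep[t][q].id;
    }
  return out;
}
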