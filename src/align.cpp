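#include <Rcpp.h>
#include <cctype>
#include <cmath>
#include <cstdlib>
#include <limits>
#include <string>
#include <vector>

using namespace Rcpp;

// IUPAC nucleotide codes as bitmasks over {A=1, C=2, G=4, T=8}.
// A column is a match iff the two base sets intersect; '-' never matches.
static int iupac_tab[256];
static bool iupac_init_done = false;

static void iupac_init() {
  if (iupac_init_done) return;
  for (int i = 0; i < 256; ++i) iupac_tab[i] = 0;
  struct { char c; int m; } codes[] = {
    {'A', 1}, {'C', 2}, {'G', 4}, {'T', 8}, {'U', 8},
    {'R', 1 | 4}, {'Y', 2 | 8}, {'S', 2 | 4}, {'W', 1 | 8},
    {'K', 4 | 8}, {'M', 1 | 2}, {'B', 2 | 4 | 8}, {'D', 1 | 4 | 8},
    {'H', 1 | 2 | 8}, {'V', 1 | 2 | 4}, {'N', 15}
  };
  for (auto &cd : codes) {
    iupac_tab[(unsigned char)cd.c] = cd.m;
    iupac_tab[(unsigned char)std::tolower(cd.c)] = cd.m;
  }
  iupac_init_done = true;
}

struct AlnOut {
  double score;
  int matches, mismatches, internal_gaps, end_gaps, max_gap_run;
  std::string aligned_a, aligned_b;
};

template <typename S> static inline S neg_inf() {
  return std::numeric_limits<S>::lowest() / 4;
}

// Needleman-Wunsch with linear gap penalty. free_ends = true gives the
// semi-global (overlap) variant: end gaps score 0 and the end cell is the
// best of the last row/column; free_ends = false is plain global alignment
// (end gaps penalized and counted as gap columns, end cell (m, n)).
// Traceback tie order: diagonal > up (gap in b) > left (gap in a).
// End cell ties (free ends): larger i, then larger j.
// band < 0 means full DP; otherwise cells with |i - j| > band + |m - n|
// are excluded. Templated on the score type: integral scoring schemes run
// in int arithmetic, arbitrary ones in double; results are identical for
// integral schemes.
template <typename S>
static void align_core(const std::string &a, const std::string &b,
                       S match, S mismatch, S gap,
                       int band, bool free_ends,
                       AlnOut &out, bool need_strings) {
  iupac_init();
  const S NEG = neg_inf<S>();
  const int m = (int)a.size(), n = (int)b.size();
  const size_t stride = (size_t)n + 1;
  int W = (band < 0) ? (m > n ? m : n) : band + std::abs(m - n);

  // Workspaces are only grown, never re-zeroed: every cell the DP or the
  // traceback can touch is written below (out-of-band neighbours are
  // fenced with NEG sentinels), so stale values from a previous call
  // never leak.
  static std::vector<S> H;
  static std::vector<signed char> T;
  const size_t need = (size_t)(m + 1) * stride;
  if (H.size() < need) H.resize(need);
  if (T.size() < need) T.resize(need);
  if (free_ends) {
    for (int j = 0; j <= n; ++j) H[j] = 0;
    for (int i = 0; i <= m; ++i) H[i * stride] = 0;
  } else {
    for (int j = 0; j <= n; ++j) H[j] = (S)j * gap;
    for (int i = 0; i <= m; ++i) H[i * stride] = (S)i * gap;
  }

  static std::vector<int> bmask;
  if (bmask.size() < (size_t)n) bmask.resize(n);
  for (int j = 0; j < n; ++j) bmask[j] = iupac_tab[(unsigned char)b[j]];

  for (int i = 1; i <= m; ++i) {
    const int jlo = std::max(1, i - W), jhi = std::min(n, i + W);
    const int ma = iupac_tab[(unsigned char)a[i - 1]];
    const size_t r = (size_t)i * stride, rp = (size_t)(i - 1) * stride;
    if (jlo > 1) H[r + jlo - 1] = NEG;          // left fence
    // cell (i, jhi) reads H[i-1][jhi]; fence it if the previous row's band
    // did not reach that column (row 0 is fully initialized)
    if (i > 1 && jhi > std::min(n, (i - 1) + W)) H[rp + jhi] = NEG;
    S left = H[r + jlo - 1];
    S diag = H[rp + jlo - 1];
    for (int j = jlo; j <= jhi; ++j) {
      const S up = H[rp + j];
      const S d = diag + ((ma & bmask[j - 1]) ? match : mismatch);
      const S u = up + gap;
      const S l = left + gap;
      // branchless selection, priority diagonal > up > left
      const S du = (u > d) ? u : d;
      const signed char dir_du = (u > d) ? (signed char)1 : (signed char)0;
      const S best = (l > du) ? l : du;
      const signed char dir = (l > du) ? (signed char)2 : dir_du;
      H[r + j] = best;
      T[r + j] = dir;
      left = best;
      diag = up;
    }
  }

  // pick end cell (scanning only cells the banded DP actually wrote)
  S bs = NEG;
  int bi = -1, bj = -1;
  if (free_ends) {
    const int jlo_m = std::max(0, m - W), jhi_m = std::min(n, m + W);
    for (int j = jlo_m; j <= jhi_m; ++j) {
      S v = H[(size_t)m * stride + j];
      if (v <= NEG / 2) continue;
      if (v > bs || (v == bs && (m > bi || (m == bi && j > bj)))) {
        bs = v; bi = m; bj = j;
      }
    }
    if (H[0] > bs) { bs = H[0]; bi = 0; bj = 0; } // zero-overlap fallback
    const int ilo_n = std::max(0, n - W), ihi_n = std::min(m, n + W);
    for (int i = ilo_n; i <= ihi_n; ++i) {
      S v = H[(size_t)i * stride + n];
      if (v <= NEG / 2) continue;
      if (v > bs || (v == bs && (i > bi || (i == bi && n > bj)))) {
        bs = v; bi = i; bj = n;
      }
    }
  } else {
    bs = H[(size_t)m * stride + n];
    bi = m; bj = n;
  }

  out.score = (double)bs;
  int i = bi, j = bj;
  int matches = 0, mism = 0, igap = 0, max_run = 0, cur_run = 0;
  std::string ra, rb; // internal region, reversed
  while (true) {
    if (free_ends) { if (i == 0 || j == 0) break; }
    else { if (i == 0 && j == 0) break; }
    signed char d;
    if (i > 0 && j > 0) d = T[(size_t)i * stride + j];
    else d = (i > 0) ? 1 : 2;   // global: walk row 0 / column 0
    if (d == 3) break; // unreachable in practice; guard
    if (d == 0) {
      bool is_match = (iupac_tab[(unsigned char)a[i - 1]] &
                       iupac_tab[(unsigned char)b[j - 1]]) != 0;
      if (is_match) ++matches; else ++mism;
      if (need_strings) { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); }
      cur_run = 0;
      --i; --j;
    } else if (d == 1) {
      ++igap; ++cur_run; if (cur_run > max_run) max_run = cur_run;
      if (need_strings) { ra.push_back(a[i - 1]); rb.push_back('-'); }
      --i;
    } else {
      ++igap; ++cur_run; if (cur_run > max_run) max_run = cur_run;
      if (need_strings) { ra.push_back('-'); rb.push_back(b[j - 1]); }
      --j;
    }
  }

  const int lead = i + j;          // one of i, j is 0 at this point
  const int trail = (m - bi) + (n - bj);
  out.matches = matches;
  out.mismatches = mism;
  out.internal_gaps = igap;
  out.end_gaps = lead + trail;
  out.max_gap_run = max_run;

  if (need_strings) {
    std::string fa, fb;
    fa.reserve(lead + ra.size() + trail);
    fb.reserve(lead + ra.size() + trail);
    // leading end gaps
    for (int k = 0; k < i; ++k) { fa.push_back(a[k]); fb.push_back('-'); }
    for (int k = 0; k < j; ++k) { fa.push_back('-'); fb.push_back(b[k]); }
    // internal region
    for (size_t k = ra.size(); k-- > 0;) {
      fa.push_back(ra[k]); fb.push_back(rb[k]);
    }
    // trailing end gaps
    for (int k = bi; k < m; ++k) { fa.push_back(a[k]); fb.push_back('-'); }
    for (int k = bj; k < n; ++k) { fa.push_back('-'); fb.push_back(b[k]); }
    out.aligned_a = fa;
    out.aligned_b = fb;
  }
}

static inline bool integral_scheme(double match, double mismatch,
                                   double gap) {
  auto ok = [](double x) {
    return std::floor(x) == x && std::fabs(x) < 1e6;
  };
  return ok(match) && ok(mismatch) && ok(gap);
}

static void run_align(const std::string &a, const std::string &b,
                      double match, double mismatch, double gap,
                      int band, bool free_ends,
                      AlnOut &out, bool need_strings) {
  if (integral_scheme(match, mismatch, gap)) {
    align_core<int>(a, b, (int)match, (int)mismatch, (int)gap, band,
                    free_ends, out, need_strings);
  } else {
    align_core<double>(a, b, match, mismatch, gap, band, free_ends, out,
                       need_strings);
  }
}

static double identity_of(const AlnOut &o) {
  const int denom = o.matches + o.mismatches + o.internal_gaps;
  return denom > 0 ? (double)o.matches / denom : 0.0;
}

// The DP is run on the lexicographically smaller sequence first and the
// gapped strings swapped back afterwards: score-equivalent (co-optimal)
// tracebacks can otherwise make the reported identity depend on argument
// order; canonicalizing the pair makes identity exactly symmetric.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap, int band,
                  bool free_ends) {
  AlnOut o;
  const bool swapped = b < a;
  if (swapped) {
    run_align(b, a, match, mismatch, gap, band, free_ends, o, true);
    std::swap(o.aligned_a, o.aligned_b);
  } else {
    run_align(a, b, match, mismatch, gap, band, free_ends, o, true);
  }
  return List::create(
    _["aligned_a"] = o.aligned_a,
    _["aligned_b"] = o.aligned_b,
    _["score"] = o.score,
    _["matches"] = o.matches,
    _["mismatches"] = o.mismatches,
    _["internal_gap_columns"] = o.internal_gaps,
    _["end_gap_columns"] = o.end_gaps,
    _["max_internal_gap_run"] = o.max_gap_run,
    _["identity"] = identity_of(o));
}

// [[Rcpp::export]]
NumericVector nw_identity_many_cpp(std::string query, CharacterVector refs,
                                   double match, double mismatch, double gap,
                                   int band) {
  const int n = refs.size();
  NumericVector out(n);
  AlnOut o;
  for (int k = 0; k < n; ++k) {
    std::string r = as<std::string>(refs[k]);
    if (r < query) run_align(r, query, match, mismatch, gap, band, true, o,
                             false);
    else run_align(query, r, match, mismatch, gap, band, true, o, false);
    out[k] = identity_of(o);
  }
  return out;
}

// Pairwise linkage for single-linkage MOTU clustering: reads i and j link
// iff their end-to-end (global) alignment has <= max_mismatch mismatch
// columns and no gap run longer than max_mismatch. Global (not free-end)
// alignment is used so unrelated reads cannot link through a short
// high-identity overlap.
// [[Rcpp::export]]
LogicalMatrix nw_link_pairs_cpp(CharacterVector seqs, int max_mismatch,
                                double match, double mismatch, double gap,
                                int band) {
  const int n = seqs.size();
  LogicalMatrix out(n, n);
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  AlnOut o;
  for (int i = 0; i < n; ++i) {
    out(i, i) = true;
    for (int j = i + 1; j < n; ++j) {
      if (ss[j] < ss[i]) run_align(ss[j], ss[i], match, mismatch, gap, band,
                                   false, o, false);
      else run_align(ss[i], ss[j], match, mismatch, gap, band, false, o,
                     false);
      bool linked = (o.mismatches <= max_mismatch) &&
                    (o.max_gap_run <= max_mismatch);
      out(i, j) = linked;
      out(j, i) = linked;
    }
  }
  return out;
}
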