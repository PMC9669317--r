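#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <limits>

using namespace Rcpp;

// Needleman-Wunsch / Gotoh global alignment with affine gaps.
// Scoring: match +1, mismatch -1, gap open -2 (first gapped column),
// gap extend -1 (each additional column).
// Identity is reported as 100 * matches / alignment columns, where columns
// belonging to terminal (leading/trailing) gap runs are excluded from the
// denominator. Traceback ties are resolved deterministically with priority
// diagonal > gap-in-b (consume a) > gap-in-a (consume b), and predecessor
// state priority M > X > Y, so results are reproducible bit-for-bit.

static const int NEG_INF = std::numeric_limits<int>::min() / 4;
static const int MATCH = 1, MISMATCH = -1, GAP_OPEN = -2, GAP_EXT = -1;

// state codes
enum { SM = 0, SX = 1, SY = 2 };

struct AlnStats {
  int matches;
  int columns;          // total alignment columns
  int terminal_gaps;    // columns in leading/trailing gap runs
};

// A provably exact band: any alignment whose path reaches i - j > Dpos has
// at least Dpos deletion columns, so its score is at most n - 2*Dpos, which
// is strictly below the gapless baseline score S0 once
// Dpos = floor((n - S0) / 2) + 1 (gap cost per column >= 1 under this
// scheme); symmetrically for j - i and insertions. All optimal paths
// therefore lie strictly inside the band and the banded DP — including its
// deterministic tie-breaks — is identical to the full matrix.
static AlnStats gotoh_align(const std::string& a0, const std::string& b0) {
  // canonicalise argument order (byte-wise) so that tie-breaking between
  // equally optimal alignments cannot make the identity asymmetric
  const bool swapped = b0 < a0;
  const std::string& a = swapped ? b0 : a0;
  const std::string& b = swapped ? a0 : b0;
  const int n = (int)a.size(), m = (int)b.size();

  // gapless baseline: overlap the prefixes, pay one terminal gap
  int overlap = std::min(n, m), matches0 = 0;
  for (int t = 0; t < overlap; ++t) if (a[t] == b[t]) ++matches0;
  int diff = std::abs(n - m);
  int s0 = 2 * matches0 - overlap - (diff > 0 ? diff + 1 : 0);
  int dpos = (n - s0) / 2 + 1;       // max allowed i - j
  int dneg = (m - s0) / 2 + 1;       // max allowed j - i
  if (dpos > n) dpos = n;
  if (dneg > m) dneg = m;

  // Lexicographic objective: maximize the alignment score, then the number
  // of terminal-gap columns (so equal-score alignments prefer gap runs at
  // the ends; an exact substring then scores identity 100). A gap move on a
  // boundary row/column is exactly a terminal-gap column, so the tie-break
  // is per-move decomposable: values are score * W + terminal_gap_columns
  // with W larger than any possible column count.
  const int W = 4 * (n + m + 2);
  const int MATCHW = MATCH * W, MISW = MISMATCH * W;
  const int OPENW = GAP_OPEN * W, EXTW = GAP_EXT * W;

  // rolling value rows; packed traceback (2 bits per state per cell)
  std::vector<int> pm(m + 1), px(m + 1), py(m + 1);
  std::vector<int> cm(m + 1), cx(m + 1), cy(m + 1);
  std::vector<uint8_t> ptr((size_t)(n + 1) * (m + 1), 0);

  // row 0: leading gaps in a (Y moves at i == 0) are terminal columns
  std::fill(pm.begin(), pm.end(), NEG_INF);
  std::fill(px.begin(), px.end(), NEG_INF);
  std::fill(py.begin(), py.end(), NEG_INF);
  pm[0] = 0;
  {
    int jmax0 = std::min(m, dneg);
    for (int j = 1; j <= jmax0; ++j) {
      py[j] = ((j == 1) ? OPENW : py[j - 1] + EXTW) + 1;
      ptr[j] = (uint8_t)(SY << 4);
    }
  }

  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * (m + 1);
    const int jlo = std::max(0, i - dpos);
    const int jhi = std::min(m, i + dneg);
    std::fill(cm.begin(), cm.end(), NEG_INF);
    std::fill(cx.begin(), cx.end(), NEG_INF);
    std::fill(cy.begin(), cy.end(), NEG_INF);
    if (jlo == 0) {
      // leading gaps in b (X moves at j == 0) are terminal columns
      cx[0] = ((i == 1) ? OPENW : px[0] + EXTW) + 1;
      ptr[row] = (uint8_t)(SX << 2);
    }
    const char ai = a[i - 1];
    for (int j = std::max(1, jlo); j <= jhi; ++j) {
      // M: consume a[i-1], b[j-1]
      int s = (ai == b[j - 1]) ? MATCHW : MISW;
      int best = pm[j - 1]; int bpM = SM;
      if (px[j - 1] > best) { best = px[j - 1]; bpM = SX; }
      if (py[j - 1] > best) { best = py[j - 1]; bpM = SY; }
      cm[j] = best + s;

      // X: consume a[i-1] against a gap; terminal when b is exhausted
      const int xb = (j == m) ? 1 : 0;
      best = pm[j] + OPENW; int bpX = SM;
      if (px[j] + EXTW > best) { best = px[j] + EXTW; bpX = SX; }
      if (py[j] + OPENW > best) { best = py[j] + OPENW; bpX = SY; }
      cx[j] = best + xb;

      // Y: consume b[j-1] against a gap; terminal when a is exhausted
      const int yb = (i == n) ? 1 : 0;
      best = cm[j - 1] + OPENW; int bpY = SM;
      if (cx[j - 1] + OPENW > best) { best = cx[j - 1] + OPENW; bpY = SX; }
      if (cy[j - 1] + EXTW > best) { best = cy[j - 1] + EXTW; bpY = SY; }
      cy[j] = best + yb;

      ptr[row + j] = (uint8_t)(bpM | (bpX << 2) | (bpY << 4));
    }
    std::swap(pm, cm); std::swap(px, cx); std::swap(py, cy);
  }

  // choose final state, priority M > X > Y on ties
  int state = SM, bestScore = pm[m];
  if (px[m] > bestScore) { bestScore = px[m]; state = SX; }
  if (py[m] > bestScore) { bestScore = py[m]; state = SY; }

  // traceback: 0 = diag column, 1 = gap column (a consumed), 2 = gap column (b consumed)
  std::vector<uint8_t> cols;
  cols.reserve(n + m);
  std::vector<uint8_t> colmatch;
  colmatch.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const uint8_t pk = ptr[(size_t)i * (m + 1) + j];
    if (state == SM) {
      cols.push_back(0);
      colmatch.push_back(a[i - 1] == b[j - 1] ? 1 : 0);
      state = pk & 3; --i; --j;
    } else if (state == SX) {
      cols.push_back(1);
      colmatch.push_back(0);
      state = (pk >> 2) & 3; --i;
    } else {
      cols.push_back(2);
      colmatch.push_back(0);
      state = (pk >> 4) & 3; --j;
    }
  }
  // cols is reversed; terminal runs are at both ends either way
  int total = (int)cols.size();
  int matches = 0;
  for (uint8_t mh : colmatch) matches += mh;
  int lead = 0, trail = 0;
  // in reversed order, front of vector = end of alignment
  while (trail < total && cols[trail] != 0) ++trail;
  if (trail < total) {
    int k = total - 1;
    while (k >= 0 && cols[k] != 0) { ++lead; --k; }
  } else {
    lead = 0; // alignment is all gaps; count once
  }
  AlnStats st;
  st.matches = matches;
  st.columns = total;
  st.terminal_gaps = (trail >= total) ? total : (lead + trail);
  return st;
}

static double identity_from_stats(const AlnStats& st) {
  int denom = st.columns - st.terminal_gaps;
  if (denom <= 0) return 0.0;
  return 100.0 * (double)st.matches / (double)denom;
}

// [[Rcpp::export(name = ".cpp_global_identity")]]
List cpp_global_identity(std::string a, std::string b) {
  if (a.empty() || b.empty())
    stop("sequences must be non-empty");
  AlnStats st = gotoh_align(a, b);
  return List::create(
    _["identity"] = identity_from_stats(st),
    _["matches"] = st.matches,
    _["columns"] = st.columns,
    _["terminal_gap_columns"] = st.terminal_gaps);
}

// [[Rcpp::export(name = ".cpp_identity_many")]]
NumericVector cpp_identity_many(std::string query, CharacterVector refs) {
  if (query.empty()) stop("query must be non-empty");
  int n = refs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(refs[i]);
    if (r.empty()) stop("reference sequences must be non-empty");
    AlnStats st = gotoh_align(query, r);
    out[i] = identity_from_stats(st);
    if (i % 8 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Primer scoring: semi-global placement of an IUPAC-degenerate primer on a
// template, minimizing the overall weighted score (OWS). The last five primer
// bases are the 3' region. Penalties: non-3' mismatch 0.40, 3' mismatch 1.00,
// terminal-base mismatch 3.00 (replacing the generic 3' penalty), non-3' gap
// 1.00 per gapped base, 3' gap 3.00 per gapped base. Traceback prefers
// diagonal > primer-base gap > template-base gap, so a tying mismatch is
// reported rather than a gap.

static int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
    case 'U': return 8;
    case 'R': return 1 | 4; case 'Y': return 2 | 8; case 'S': return 2 | 4;
    case 'W': return 1 | 8; case 'K': return 4 | 8; case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8; case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8; case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default: return 0;
  }
}

// [[Rcpp::export(name = ".cpp_score_primer")]]
List cpp_score_primer(std::string primer, std::string tmpl) {
  const int m = (int)primer.size(), n = (int)tmpl.size();
  if (m < 1 || n < 1) stop("primer and template must be non-empty");

  std::vector<int> pmask(m), tmask(n);
  for (int i = 0; i < m; ++i) pmask[i] = iupac_mask(primer[i]);
  for (int j = 0; j < n; ++j) tmask[j] = iupac_mask(tmpl[j]);

  // penalty helpers; primer positions are 1-based from the 5' end
  auto mm_pen = [&](int i) {          // mismatch consuming primer base i
    if (i == m) return 3.0;           // terminal base (replacement convention)
    if (i > m - 5) return 1.0;        // within last five, not terminal
    return 0.4;
  };
  auto del_pen = [&](int i) {         // primer base i aligned to a gap
    return (i > m - 5) ? 3.0 : 1.0;
  };
  auto ins_pen = [&](int i) {         // extra template base between primer i and i+1
    return (i >= m - 4) ? 3.0 : 1.0;  // falls inside the last-five block
  };

  const double INF = std::numeric_limits<double>::infinity();
  // D[i][j]: min cost of aligning primer[1..i] with some template window
  // ending at template position j (template consumed through j). Start free.
  std::vector<std::vector<double>> D(m + 1, std::vector<double>(n + 1, INF));
  std::vector<std::vector<uint8_t>> P(m + 1, std::vector<uint8_t>(n + 1, 0));
  // move codes: 1 = diag, 2 = primer-base gap (up), 3 = template insertion (left)
  for (int j = 0; j <= n; ++j) D[0][j] = 0.0;

  for (int i = 1; i <= m; ++i) {
    // j = 0: only primer-base gaps possible
    D[i][0] = D[i - 1][0] + del_pen(i);
    P[i][0] = 2;
    for (int j = 1; j <= n; ++j) {
      double sub = (pmask[i - 1] & tmask[j - 1]) ? 0.0 : mm_pen(i);
      double best = D[i - 1][j - 1] + sub; uint8_t mv = 1;
      double up = D[i - 1][j] + del_pen(i);
      if (up < best) { best = up; mv = 2; }
      if (i >= 1 && i <= m - 1) {
        double lf = D[i][j - 1] + ins_pen(i);
        if (lf < best) { best = lf; mv = 3; }
      }
      D[i][j] = best; P[i][j] = mv;
    }
  }

  // minimal cost over all template end positions; rightmost end on ties so
  // that a terminal-base mismatch is preferred over an equal-cost terminal gap
  int jbest = n; double best = INF;
  for (int j = n; j >= 0; --j) {
    if (D[m][j] < best) { best = D[m][j]; jbest = j; }
  }

  // traceback to classify events
  int non3_mm = 0, tp_mm = 0, last_mm = 0, non3_gap = 0, tp_gap = 0;
  int i = m, j = jbest;
  int site_start = 0, site_end = jbest; // 1-based template span of the placement
  while (i > 0) {
    uint8_t mv = P[i][j];
    if (mv == 1) {
      if (!(pmask[i - 1] & tmask[j - 1])) {
        if (i == m) last_mm += 1;
        else if (i > m - 5) tp_mm += 1;
        else non3_mm += 1;
      }
      --i; --j;
    } else if (mv == 2) {
      if (i > m - 5) tp_gap += 1; else non3_gap += 1;
      --i;
    } else {
      if (i >= m - 4) tp_gap += 1; else non3_gap += 1;
      --j;
    }
  }
  site_start = j + 1;

  return List::create(
    _["ows"] = best,
    _["non3_mismatches"] = non3_mm,
    _["three_prime_mismatches"] = tp_mm,
    _["last_base_mismatch"] = (last_mm > 0),
    _["non3_gaps"] = non3_gap,
    _["three_prime_gaps"] = tp_gap,
    _["start"] = site_start,
    _["end"] = site_end);
}
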