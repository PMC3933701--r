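#include <Rcpp.h>
using namespace Rcpp;

// Sequences are pre-encoded in R as IUPAC bitmasks: A=1, C=2, G=4, T=8,
// ambiguity codes are unions, gap/unknown-illegal = 0. A target base t is
// covered by a primer base p iff every concretization of t lies in p's
// expansion, i.e. (t & ~p) == 0 (subset rule).

// Scan every window of `subject` against `primer`. For each window report
// the mismatch count (positions failing the subset rule) and the anchor run:
// the perfect-match run from the primer 3' terminus. For a plus-strand hit of
// a forward primer the 3' end is the window's right end (anchor_left=false);
// for the plus-strand image of a reverse primer (already reverse-complemented
// by the caller) the 3' end maps to the window's left end (anchor_left=true).
// [[Rcpp::export]]
IntegerMatrix scan_windows_cpp(IntegerVector primer, IntegerVector subject,
                               bool anchor_left) {
  const int L = primer.size(), n = subject.size();
  const int nw = n - L + 1;
  if (nw <= 0) return IntegerMatrix(0, 3);
  IntegerMatrix out(nw, 3);
  for (int s = 0; s < nw; ++s) {
    int mm = 0;
    for (int k = 0; k < L; ++k)
      if (subject[s + k] & ~primer[k]) ++mm;
    int run = 0;
    if (anchor_left) {
      while (run < L && !(subject[s + run] & ~primer[run])) ++run;
    } else {
      while (run < L && !(subject[s + L - 1 - run] & ~primer[L - 1 - run])) ++run;
    }
    out(s, 0) = s + 1;   // 1-based window start
    out(s, 1) = mm;
    out(s, 2) = run;
  }
  return out;
}

// Global alignment of two mask-encoded sequences, linear gap penalty.
// Match iff expansions intersect: (a & b) != 0. Traceback tie-break
// diagonal > up > left (up consumes a row of `a`, left a column of `b`).
// Returns 1-based index paths with 0 marking a gap.
// [[Rcpp::export]]
List nw_pair_cpp(IntegerVector a, IntegerVector b,
                 double match, double mismatch, double gap) {
  const int m = a.size(), n = b.size();
  std::vector<double> prev(n + 1), cur(n + 1);
  std::vector<uint8_t> T((size_t)(m + 1) * (n + 1));  // 0 diag, 1 up, 2 left
  for (int j = 1; j <= n; ++j) { prev[j] = j * gap; T[j] = 2; }
  for (int i = 1; i <= m; ++i) {
    cur[0] = i * gap;
    T[(size_t)i * (n + 1)] = 1;
    const int av = a[i - 1];
    uint8_t *Trow = &T[(size_t)i * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      double sd = prev[j - 1] + ((av & b[j - 1]) ? match : mismatch);
      double su = prev[j] + gap;
      double sl = cur[j - 1] + gap;
      double best = sd; uint8_t tb = 0;
      if (su > best) { best = su; tb = 1; }
      if (sl > best) { best = sl; tb = 2; }
      cur[j] = best; Trow[j] = tb;
    }
    std::swap(prev, cur);
  }
  std::vector<int> ai, bi;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    uint8_t tb = T[(size_t)i * (n + 1) + j];
    if (tb == 0) { ai.push_back(i); bi.push_back(j); --i; --j; }
    else if (tb == 1) { ai.push_back(i); bi.push_back(0); --i; }
    else { ai.push_back(0); bi.push_back(j); --j; }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = prev[n],
                      _["ai"] = wrap(ai), _["bi"] = wrap(bi));
}

// p-distance over the nw_pair_cpp alignment of two ungapped sequences:
// identical aligned residue pairs / aligned columns (gaps count as
// differences). Used for guide-tree distances without materialising paths.
// [[Rcpp::export]]
double nw_guide_dist_cpp(IntegerVector a, IntegerVector b,
                         double match, double mismatch, double gap) {
  List al = nw_pair_cpp(a, b, match, mismatch, gap);
  IntegerVector ai = al["ai"], bi = al["bi"];
  int ident = 0;
  for (int k = 0; k < ai.size(); ++k) {
    if (ai[k] > 0 && bi[k] > 0 && a[ai[k] - 1] == b[bi[k] - 1]) ++ident;
  }
  return 1.0 - (double)ident / ai.size();
}

// Profile-profile global alignment for progressive MSA. Profiles are 5 x L
// matrices of column fractions over (A, C, G, T, gap). Column score is the
// expected pair score; a new gap column is charged gap * (residue fraction)
// of the opposing column so already-gappy columns cost less to skip.
// Same traceback tie-break as nw_pair_cpp.
// [[Rcpp::export]]
List nw_profile_cpp(NumericMatrix pa, NumericMatrix pb,
                    double match, double mismatch, double gap) {
  const int m = pa.ncol(), n = pb.ncol();
  NumericVector resa(m), resb(n);  // non-gap fraction per column
  for (int i = 0; i < m; ++i) resa[i] = 1.0 - pa(4, i);
  for (int j = 0; j < n; ++j) resb[j] = 1.0 - pb(4, j);
  // expected pair score between two columns decomposes as
  // mismatch * ra * rb + (match - mismatch) * sum_x fa[x] * fb[x]
  std::vector<double> prev(n + 1), cur(n + 1);
  std::vector<uint8_t> T((size_t)(m + 1) * (n + 1));
  for (int j = 1; j <= n; ++j) { prev[j] = prev[j - 1] + gap * resb[j - 1]; T[j] = 2; }
  for (int i = 1; i <= m; ++i) {
    const double ra = resa[i - 1], ga = pa(4, i - 1);
    const double fa0 = pa(0, i - 1), fa1 = pa(1, i - 1),
                 fa2 = pa(2, i - 1), fa3 = pa(3, i - 1);
    cur[0] = prev[0] + gap * ra;  // column-0 boundary accumulates row gaps
    uint8_t *Trow = &T[(size_t)i * (n + 1)];
    Trow[0] = 1;
    for (int j = 1; j <= n; ++j) {
      const double rb = resb[j - 1];
      double dot = fa0 * pb(0, j - 1) + fa1 * pb(1, j - 1) +
                   fa2 * pb(2, j - 1) + fa3 * pb(3, j - 1);
      double col = mismatch * ra * rb + (match - mismatch) * dot +
                   gap * (ga * rb + pb(4, j - 1) * ra);
      double sd = prev[j - 1] + col;
      double su = prev[j] + gap * ra;
      double sl = cur[j - 1] + gap * rb;
      double best = sd; uint8_t tb = 0;
      if (su > best) { best = su; tb = 1; }
      if (sl > best) { best = sl; tb = 2; }
      cur[j] = best; Trow[j] = tb;
    }
    std::swap(prev, cur);
  }
  std::vector<int> ai, bi;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    uint8_t tb = T[(size_t)i * (n + 1) + j];
    if (tb == 0) { ai.push_back(i); bi.push_back(j); --i; --j; }
    else if (tb == 1) { ai.push_back(i); bi.push_back(0); --i; }
    else { ai.push_back(0); bi.push_back(j); --j; }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = prev[n],
                      _["ai"] = wrap(ai), _["bi"] = wrap(bi));
}

// Pairwise p-distance with pairwise deletion over selected columns.
// `codes` is an n x C integer matrix of IUPAC masks (0 = gap); `cols` gives
// 1-based column indices (possibly with repeats, for bootstrap resampling).
// Distance is literal code inequality, not expansion intersection. Pairs with
// zero comparable columns get NaN; the R caller raises the error.
// [[Rcpp::export]]
NumericMatrix pdist_cpp(IntegerMatrix codes, IntegerVector cols) {
  const int n = codes.nrow(), C = cols.size();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      long comp = 0, diff = 0;
      for (int c = 0; c < C; ++c) {
        int cc = cols[c] - 1;
        int x = codes(i, cc), y = codes(j, cc);
        if (x && y) { ++comp; if (x != y) ++diff; }
      }
      double v = comp ? (double)diff / comp : R_NaN;
      d(i, j) = v; d(j, i) = v;
    }
  }
  return d;
}
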