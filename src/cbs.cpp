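#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Maximum-overlap assignment of reads to sorted amplicons on one chromosome.
// Ties: smaller start wins, then smaller id. Zero overlap -> NA.
// [[Rcpp::export]]
IntegerVector assign_reads_cpp(NumericVector rstart, NumericVector rend,
                               NumericVector astart, NumericVector aend,
                               IntegerVector aid) {
  int nr = rstart.size(), na = astart.size();
  IntegerVector out(nr, NA_INTEGER);
  for (int r = 0; r < nr; ++r) {
    double best = 0.0; int besti = -1;
    for (int a = 0; a < na; ++a) {
      if (astart[a] >= rend[r]) break;  // sorted by start
      double ov = std::min(rend[r], aend[a]) - std::max(rstart[r], astart[a]);
      if (ov > best) { best = ov; besti = a; }
      // ties resolved implicitly: first (smaller start, then id) is kept
    }
    if (besti >= 0) out[r] = aid[besti];
  }
  return out;
}

// Weighted circular max-shift statistic for one segment.
// x: values, w: weights (1/sigma_i^2). Considers every arc (i+1..j) vs its
// complement and returns the max |Z| with Z = (m_arc - m_comp) /
// sqrt(1/W_arc + 1/W_comp), plus the arg-max arc bounds (1-based, inclusive).
static double max_arc_stat(const std::vector<double>& cx,
                           const std::vector<double>& cw,
                           int n, int minseg, int* bi, int* bj) {
  double tot_x = cx[n], tot_w = cw[n];
  double best = -1.0;
  for (int i = 0; i <= n - minseg; ++i) {
    if (i != 0 && i < minseg) continue;        // left flank >= minseg or empty
    for (int j = i + minseg; j <= n; ++j) {
      if (j != n && n - j < minseg) continue;  // right flank >= minseg or empty
      int arclen = j - i;
      int comp = n - arclen;
      if (comp < minseg) continue;
      double wa = cw[j] - cw[i];
      double wc = tot_w - wa;
      if (wa <= 0.0 || wc <= 0.0) continue;
      double ma = (cx[j] - cx[i]) / wa;
      double mc = (tot_x - (cx[j] - cx[i])) / wc;
      double z = std::fabs(ma - mc) / std::sqrt(1.0 / wa + 1.0 / wc);
      if (z > best) { best = z; *bi = i + 1; *bj = j; }
    }
  }
  return best;
}

// One CBS split attempt with permutation acceptance.
// Returns list(stat, i, j, p). i..j is the best arc (1-based inclusive into
// x); p estimated from nperm joint permutations of (x, w) pairs, with early
// exit once rejection is impossible at level alpha.
// [[Rcpp::export]]
List cbs_split_cpp(NumericVector x, NumericVector w, int nperm, double alpha,
                   int minseg, int seed_offset) {
  int n = x.size();
  std::vector<double> cx(n + 1, 0.0), cw(n + 1, 0.0);
  for (int k = 0; k < n; ++k) {
    cx[k + 1] = cx[k] + x[k] * w[k];
    cw[k + 1] = cw[k] + w[k];
  }
  int bi = 0, bj = 0;
  double obs = max_arc_stat(cx, cw, n, minseg, &bi, &bj);
  if (obs < 0.0)
    return List::create(_["stat"] = NA_REAL, _["i"] = NA_INTEGER,
                        _["j"] = NA_INTEGER, _["p"] = 1.0);
  // permutation null distribution of the max statistic
  RNGScope scope;               // use R's RNG -> reproducible via set.seed
  (void)seed_offset;
  int exceed = 0, done = 0;
  int needed = (int)std::floor(alpha * nperm) + 1;  // exceedances to accept H0
  std::vector<int> idx(n);
  for (int k = 0; k < n; ++k) idx[k] = k;
  std::vector<double> px(n), pw(n), pcx(n + 1, 0.0), pcw(n + 1, 0.0);
  for (int p = 0; p < nperm; ++p) {
    // Fisher-Yates using R unif_rand
    for (int k = n - 1; k > 0; --k) {
      int r = (int)(unif_rand() * (k + 1));
      if (r > k) r = k;
      std::swap(idx[k], idx[r]);
    }
    for (int k = 0; k < n; ++k) { px[k] = x[idx[k]]; pw[k] = w[idx[k]]; }
    for (int k = 0; k < n; ++k) {
      pcx[k + 1] = pcx[k] + px[k] * pw[k];
      pcw[k + 1] = pcw[k] + pw[k];
    }
    int di, dj;
    double st = max_arc_stat(pcx, pcw, n, minseg, &di, &dj);
    ++done;
    if (st >= obs) {
      ++exceed;
      if (exceed >= needed) break;  // cannot reach significance any more
    }
  }
  double pval = (exceed + 1.0) / (done + 1.0);
  if (exceed >= needed) pval = 1.0;  // early-exit: report as non-significant
  return List::create(_["stat"] = obs, _["i"] = bi, _["j"] = bj,
                      _["p"] = pval);
}
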