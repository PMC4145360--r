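#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Welch t statistic for the QMDR high/low pooling of one SNP subset.
//
// Cells are multilocus genotype combinations over the subset (base-3 index).
// A cell is labelled HIGH when its phenotype mean is >= the global mean of
// the samples included in this model (ties -> HIGH); samples missing a
// genotype at any subset SNP are excluded.  Degenerate poolings (an empty
// group, zero pooled spread, fewer than 2 usable samples) score 0 so that
// exhaustive scans never abort mid-search.
static double qmdr_t_one(const IntegerMatrix& g, const NumericVector& y,
                         const int* rows, int k,
                         int* cell, double* csum, int* cnt) {
  int ncell = 1;
  for (int j = 0; j < k; ++j) ncell *= 3;
  const int n = g.ncol();
  std::fill(csum, csum + ncell, 0.0);
  std::fill(cnt, cnt + ncell, 0);
  double tot = 0.0;
  int ninc = 0;
  for (int s = 0; s < n; ++s) {
    int idx = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      const int gv = g(rows[j], s);
      if (gv == NA_INTEGER) { ok = false; break; }
      idx = idx * 3 + gv;
    }
    if (ok) {
      cell[s] = idx;
      csum[idx] += y[s];
      cnt[idx] += 1;
      tot += y[s];
      ++ninc;
    } else {
      cell[s] = -1;
    }
  }
  if (ninc < 2) return 0.0;
  const double gmean = tot / ninc;
  double sh = 0, qh = 0, sl = 0, ql = 0;
  int nh = 0, nl = 0;
  for (int s = 0; s < n; ++s) {
    const int idx = cell[s];
    if (idx < 0) continue;
    const double yc = y[s] - gmean;  // centred accumulation for stability
    if (csum[idx] / cnt[idx] >= gmean) {
      sh += yc; qh += yc * yc; ++nh;
    } else {
      sl += yc; ql += yc * yc; ++nl;
    }
  }
  if (nh == 0 || nl == 0) return 0.0;
  const double mh = sh / nh, ml = sl / nl;
  double vh = nh > 1 ? (qh - nh * mh * mh) / (nh - 1) : 0.0;
  double vl = nl > 1 ? (ql - nl * ml * ml) / (nl - 1) : 0.0;
  if (vh < 0) vh = 0;
  if (vl < 0) vl = 0;
  const double se2 = vh / nh + vl / nl;
  if (se2 <= 0) return 0.0;
  return (mh - ml) / std::sqrt(se2);
}

// QMDR t statistics for a list of SNP subsets.
// g: SNP x sample dosage matrix ({0,1,2}, NA_INTEGER = missing);
// y: phenotype aligned with the columns of g;
// subsets: list of 1-based row-index vectors, each of size 1..4.
// [[Rcpp::export]]
NumericVector cpp_qmdr_scores(IntegerMatrix g, NumericVector y, List subsets) {
  if (y.size() != g.ncol())
    stop("phenotype length must equal the number of samples");
  const int nsub = subsets.size();
  NumericVector out(nsub);
  std::vector<int> cell(g.ncol());
  double csum[81];
  int cnt[81];
  int rows[4];
  for (int i = 0; i < nsub; ++i) {
    IntegerVector sub = subsets[i];
    const int k = sub.size();
    if (k < 1 || k > 4) stop("subset size must be between 1 and 4");
    for (int j = 0; j < k; ++j) {
      const int r = sub[j] - 1;
      if (r < 0 || r >= g.nrow()) stop("subset index out of range");
      rows[j] = r;
    }
    out[i] = qmdr_t_one(g, y, rows, k, cell.data(), csum, cnt);
  }
  return out;
}
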