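// Lagged maximal information coefficient, ApproxMaxMI heuristic.
//
// For every admissible grid shape (cols x rows <= B), one axis is
// partitioned (equipartition with ties kept together, or exhaustively when
// it has few distinct values) and the other axis is partitioned optimally
// by dynamic programming over value clumps. Both orientations are tried and
// the maximum of normalized mutual information I / log2(min(cols, rows))
// is returned. Ties (identical values) are never split across grid cells.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Greedy equipartition of ordered value groups (sizes cnt) into at most q
// rows, never splitting a group. Fills rowOfRank; returns realized rows.
static int equipartition(const std::vector<int>& cnt, int n, int q,
                         std::vector<int>& rowOfRank) {
  int d = (int)cnt.size();
  rowOfRank.assign(d, 0);
  int consumed = 0, currRow = 0, currSize = 0;
  double desired = (double)n / q;
  for (int rank = 0; rank < d; ++rank) {
    int s = cnt[rank];
    if (currSize != 0 && currRow < q - 1 &&
        std::fabs(currSize + s - desired) >= std::fabs(currSize - desired)) {
      ++currRow;
      currSize = 0;
      int rowsLeft = q - currRow;
      desired = (double)(n - consumed) / rowsLeft;
    }
    rowOfRank[rank] = currRow;
    currSize += s;
    consumed += s;
  }
  return currRow + 1;
}

// DP over column clumps for a fixed row assignment. Returns the best
// normalized score over column counts 2..maxl.
//   clumpOfPoint: clump index (0-based, by ascending column value) per
//     point, points ordered by column value;
//   rowOfPoint: row index per point (same ordering);
//   nrows: number of realized rows; maxl: max columns; cfac: clump factor.
static double optimize_axis(const std::vector<int>& clumpOfPoint,
                            const std::vector<int>& rowOfPoint,
                            int nclump, int nrows, int maxl, int cfac) {
  int n = (int)clumpOfPoint.size();
  if (nclump < 2 || nrows < 2 || maxl < 2) return NEG_INF;

  // superclumps: cap the number of clumps at cfac * maxl
  std::vector<int> super(nclump);
  int k = nclump;
  int cap = cfac * maxl;
  if (nclump > cap) {
    std::vector<int> csize(nclump, 0);
    for (int i = 0; i < n; ++i) csize[clumpOfPoint[i]]++;
    k = equipartition(csize, n, cap, super);
  } else {
    for (int c = 0; c < nclump; ++c) super[c] = c;
  }

  // prefix counts per row over superclumps 1..k (1-based prefixes)
  std::vector<double> np(k + 1, 0.0);
  std::vector<double> cum((k + 1) * nrows, 0.0);
  {
    std::vector<int> cnt(k * nrows, 0), tot(k, 0);
    for (int i = 0; i < n; ++i) {
      int sc = super[clumpOfPoint[i]];
      cnt[sc * nrows + rowOfPoint[i]]++;
      tot[sc]++;
    }
    for (int t = 1; t <= k; ++t) {
      np[t] = np[t - 1] + tot[t - 1];
      for (int r = 0; r < nrows; ++r)
        cum[t * nrows + r] = cum[(t - 1) * nrows + r] + cnt[(t - 1) * nrows + r];
    }
  }

  auto Hq = [&](int a, int b) {  // row entropy of points in superclumps a..b
    double tot = np[b] - np[a - 1];
    double h = 0.0;
    for (int r = 0; r < nrows; ++r) {
      double c = cum[b * nrows + r] - cum[(a - 1) * nrows + r];
      if (c > 0) {
        double p = c / tot;
        h -= p * std::log2(p);
      }
    }
    return h;
  };

  double hfull = Hq(1, k);
  std::vector<double> Fprev(k + 1, NEG_INF), Fcur(k + 1, NEG_INF);
  for (int t = 1; t <= k; ++t) Fprev[t] = -Hq(1, t);

  double best = NEG_INF;
  for (int l = 2; l <= maxl; ++l) {
    std::fill(Fcur.begin(), Fcur.end(), NEG_INF);
    for (int t = l; t <= k; ++t) {
      double bv = NEG_INF;
      for (int s = l - 1; s <= t - 1; ++s) {
        if (Fprev[s] == NEG_INF) continue;
        double v = (np[s] / np[t]) * Fprev[s] -
                   ((np[t] - np[s]) / np[t]) * Hq(s + 1, t);
        if (v > bv) bv = v;
      }
      Fcur[t] = bv;
    }
    if (Fcur[k] != NEG_INF) {
      double info = hfull + Fcur[k];
      double denom = std::log2((double)std::min(l, nrows));
      double val = info / denom;
      if (val > best) best = val;
    }
    std::swap(Fprev, Fcur);
  }
  return best;
}

// rank (0-based, ascending) of each value among its distinct values
static int dense_ranks(const std::vector<double>& v, std::vector<int>& rank,
                       std::vector<int>& cntPerRank) {
  int n = (int)v.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  rank.assign(n, 0);
  cntPerRank.clear();
  int d = -1;
  for (int j = 0; j < n; ++j) {
    if (j == 0 || v[ord[j]] != v[ord[j - 1]]) {
      ++d;
      cntPerRank.push_back(0);
    }
    rank[ord[j]] = d;
    cntPerRank[d]++;
  }
  return d + 1;
}

// Best normalized score with columns on `colv`, rows on `rowv`.
static double orientation_best(const std::vector<double>& colv,
                               const std::vector<double>& rowv,
                               int B, int cfac, int exh, bool strict) {
  int n = (int)colv.size();
  std::vector<int> colRank, colCnt, rowRank, rowCnt;
  int dcol = dense_ranks(colv, colRank, colCnt);
  int drow = dense_ranks(rowv, rowRank, rowCnt);
  if (dcol < 2 || drow < 2) return NEG_INF;

  // points ordered by column value; clump = distinct column value
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return colv[a] < colv[b]; });
  std::vector<int> clumpOfPoint(n), rowValRank(n);
  for (int j = 0; j < n; ++j) {
    clumpOfPoint[j] = colRank[ord[j]];
    rowValRank[j] = rowRank[ord[j]];
  }

  int Beff = strict ? B - 1 : B;  // grids must satisfy cols*rows <= Beff
  double best = NEG_INF;
  std::vector<int> rowOfRank(drow), rowOfPoint(n);

  if (drow <= exh && drow <= 30) {
    // enumerate every partition of the row axis (2^(drow-1) - 1 splits)
    unsigned nmask = 1u << (drow - 1);
    for (unsigned mask = 1; mask < nmask; ++mask) {
      int r = 1;
      for (int b = 0; b < drow - 1; ++b) {
        rowOfRank[b] = r - 1;
        if (mask & (1u << b)) ++r;
      }
      rowOfRank[drow - 1] = r - 1;
      if (r < 2) continue;
      int maxl = Beff / r;
      if (maxl < 2) continue;
      for (int j = 0; j < n; ++j) rowOfPoint[j] = rowOfRank[rowValRank[j]];
      double v = optimize_axis(clumpOfPoint, rowOfPoint, dcol, r, maxl, cfac);
      if (v > best) best = v;
    }
  } else {
    int qmax = Beff / 2;
    for (int q = 2; q <= qmax; ++q) {
      int r = equipartition(rowCnt, n, q, rowOfRank);
      if (r < 2) continue;
      int maxl = Beff / r;
      if (maxl < 2) continue;
      for (int j = 0; j < n; ++j) rowOfPoint[j] = rowOfRank[rowValRank[j]];
      double v = optimize_axis(clumpOfPoint, rowOfPoint, dcol, r, maxl, cfac);
      if (v > best) best = v;
    }
  }
  return best;
}

// [[Rcpp::export]]
double mic_approx_cpp(NumericVector x, NumericVector y, int B, int cfac,
                      int exhaustive_max, bool strict) {
  int n = x.size();
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  double best = orientation_best(xv, yv, B, cfac, exhaustive_max, strict);
  double b2 = orientation_best(yv, xv, B, cfac, exhaustive_max, strict);
  if (b2 > best) best = b2;
  (void)n;
  if (best == NEG_INF) return 0.0;
  if (best < 0.0) best = 0.0;
  if (best > 1.0) best = 1.0;
  return best;
}
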