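#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Extend haplotype-homozygosity groups outward from a core marker.
// Carrier haplotypes start as one group at the core (EHH(core) = 1);
// at each successive marker groups are split by the allele there and
// EHH(m) = sum_g n_g (n_g - 1) / (n (n - 1)). The walk stops at a
// chromosome end, at an inter-marker gap above max_gap, or at the first
// marker whose EHH falls below min_ehh (that marker is not emitted).
static void walk(const IntegerMatrix& hap, const std::vector<int>& rows,
                 int core, int dir, double min_ehh, double max_gap,
                 const NumericVector& pos,
                 std::vector<int>& out_col, std::vector<double>& out_ehh) {
  int nc = (int)rows.size();
  if (nc < 2) return;
  int m = hap.ncol();
  std::vector<int> grp(nc, 0);
  int ngroups = 1;
  double denom = (double)nc * (nc - 1);
  int j = core;
  while (true) {
    int nj = j + dir;
    if (nj < 0 || nj >= m) break;
    if (std::fabs(pos[nj] - pos[j]) > max_gap) break;
    std::vector<int> newgrp(nc);
    std::vector<int> remap(2 * ngroups, -1);
    int ng = 0;
    for (int i = 0; i < nc; ++i) {
      int key = grp[i] * 2 + hap(rows[i], nj);
      if (remap[key] < 0) remap[key] = ng++;
      newgrp[i] = remap[key];
    }
    std::vector<int> cnt(ng, 0);
    for (int i = 0; i < nc; ++i) cnt[newgrp[i]]++;
    double hom = 0.0;
    for (int k = 0; k < ng; ++k) hom += (double)cnt[k] * (cnt[k] - 1);
    double e = hom / denom;
    if (e < min_ehh) break;
    grp.swap(newgrp);
    ngroups = ng;
    out_col.push_back(nj);
    out_ehh.push_back(e);
    j = nj;
    if (e <= 0.0) break;
  }
}

// Full EHH curve (both directions) for the given carrier rows (0-based).
// [[Rcpp::export]]
List ehh_curve_cpp(IntegerMatrix hap, IntegerVector rows0, int core0,
                   NumericVector pos, double min_ehh, double max_gap) {
  std::vector<int> rows(rows0.begin(), rows0.end());
  std::vector<int> lc, rc;
  std::vector<double> le, re;
  walk(hap, rows, core0, -1, min_ehh, max_gap, pos, lc, le);
  walk(hap, rows, core0, +1, min_ehh, max_gap, pos, rc, re);
  int nl = (int)lc.size(), nr = (int)rc.size();
  IntegerVector cols(nl + 1 + nr);
  NumericVector ehh(nl + 1 + nr);
  for (int i = 0; i < nl; ++i) {          // left side, nearest-last: reverse
    cols[nl - 1 - i] = lc[i];
    ehh[nl - 1 - i] = le[i];
  }
  cols[nl] = core0;
  ehh[nl] = 1.0;
  for (int i = 0; i < nr; ++i) {
    cols[nl + 1 + i] = rc[i];
    ehh[nl + 1 + i] = re[i];
  }
  return List::create(_["col"] = cols, _["ehh"] = ehh);
}

// Trapezoid integral of the EHH curve over physical distance, both sides.
static double ihh_from(const IntegerMatrix& hap, const std::vector<int>& rows,
                       int core, const NumericVector& pos,
                       double min_ehh, double max_gap) {
  double area = 0.0;
  for (int dir = -1; dir <= 1; dir += 2) {
    std::vector<int> cols;
    std::vector<double> eh;
    walk(hap, rows, core, dir, min_ehh, max_gap, pos, cols, eh);
    double eprev = 1.0, pprev = pos[core];
    for (size_t t = 0; t < cols.size(); ++t) {
      double p = pos[cols[t]];
      area += 0.5 * (eprev + eh[t]) * std::fabs(p - pprev);
      eprev = eh[t];
      pprev = p;
    }
  }
  return area;
}

// Per-site integrated EHH for both core alleles: columns ihh0, ihh1, n0, n1.
// [[Rcpp::export]]
NumericMatrix ihh_scan_cpp(IntegerMatrix hap, NumericVector pos,
                           double min_ehh, double max_gap) {
  int m = hap.ncol(), n = hap.nrow();
  NumericMatrix out(m, 4);
  for (int s = 0; s < m; ++s) {
    std::vector<int> r0, r1;
    for (int i = 0; i < n; ++i) {
      if (hap(i, s) == 0) r0.push_back(i); else r1.push_back(i);
    }
    out(s, 2) = (double)r0.size();
    out(s, 3) = (double)r1.size();
    out(s, 0) = r0.size() >= 2 ? ihh_from(hap, r0, s, pos, min_ehh, max_gap) : NA_REAL;
    out(s, 1) = r1.size() >= 2 ? ihh_from(hap, r1, s, pos, min_ehh, max_gap) : NA_REAL;
  }
  return out;
}

// Per-site integrated site-specific EHH (iES), pooled over all haplotypes.
// [[Rcpp::export]]
NumericVector ies_scan_cpp(IntegerMatrix hap, NumericVector pos,
                           double min_ehh, double max_gap) {
  int m = hap.ncol(), n = hap.nrow();
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  NumericVector out(m);
  for (int s = 0; s < m; ++s)
    out[s] = n >= 2 ? ihh_from(hap, all, s, pos, min_ehh, max_gap) : NA_REAL;
  return out;
}
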