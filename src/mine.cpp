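// Maximal information coefficient (MIC) estimation.
//
// Two independent backends behind the same contract:
//   * mic_approx_cpp — the standard MINE approximation: equipartition one
//     axis, reduce the other to clumps/superclumps, dynamic programming for
//     the optimal column partition; grid sizes l*q <= B(n) = n^alpha.
//   * mic_exact_cpp  — exhaustive search: enumerate every partition of the
//     axis carrying min(l, q) <= sqrt(B) bins, and solve the other axis
//     exactly by dynamic programming over value groups.  Exact maximiser of
//     normalised grid mutual information; intended for small n (test oracle).
//
// All entropies in nats; the normalisation I / log(min(l, q)) is scale-free.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using Rcpp::NumericVector;

namespace {

std::vector<int> order_of(const NumericVector& v) {
  std::vector<int> ord(v.size());
  for (int i = 0; i < (int)v.size(); ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  return ord;
}

// Equipartition points (sorted order `ord` on values `v`) into at most q
// rows, never splitting tied values.  Returns the number of rows used and
// fills `bin` (original indexing).
int equipartition(const NumericVector& v, const std::vector<int>& ord, int q,
                  std::vector<int>& bin) {
  const int n = (int)ord.size();
  bin.assign(n, 0);
  double rowsize = (double)n / q;
  int i = 0, h = 0, curr = 0;
  while (i < n) {
    int s = 1;
    while (i + s < n && v[ord[i + s]] == v[ord[i]]) ++s;
    double t1 = std::fabs((double)h + s - rowsize);
    double t2 = std::fabs((double)h - rowsize);
    if (h != 0 && t1 >= t2 && curr < q - 1) {
      ++curr;
      h = 0;
      rowsize = (double)(n - i) / (q - curr);
    }
    for (int j = 0; j < s; ++j) bin[ord[i + j]] = curr;
    i += s;
    h += s;
  }
  return curr + 1;
}

struct ClumpTable {
  int k = 0;                          // number of clumps
  int q = 0;                          // number of rows
  std::vector<int> cum;               // cum[t], t = 0..k: points in clumps 1..t
  std::vector<int> cumhist;           // cumhist[t*q + r]: row-r points in clumps 1..t
  double seg_entropy(int s, int t) const {  // H(rows) within clumps (s, t]
    int np = cum[t] - cum[s];
    double h = 0.0;
    for (int r = 0; r < q; ++r) {
      int c = cumhist[t * q + r] - cumhist[s * q + r];
      if (c > 0) {
        double p = (double)c / np;
        h -= p * std::log(p);
      }
    }
    return h;
  }
};

// Group points by distinct value along the optimised axis, then merge
// adjacent groups pure in the same row (clumps); optionally coarsen to at
// most khat superclumps (khat <= 0 disables coarsening).
ClumpTable build_clumps(const NumericVector& v, const std::vector<int>& ord,
                        const std::vector<int>& rowbin, int q, int khat) {
  const int n = (int)ord.size();
  std::vector<int> gsize, gpure;  // per distinct-value group: size, pure row or -1
  std::vector<std::vector<int>> gh;
  int i = 0;
  while (i < n) {
    int s = 1;
    while (i + s < n && v[ord[i + s]] == v[ord[i]]) ++s;
    std::vector<int> hist(q, 0);
    for (int j = 0; j < s; ++j) hist[rowbin[ord[i + j]]]++;
    int pure = rowbin[ord[i]];
    for (int j = 1; j < s; ++j)
      if (rowbin[ord[i + j]] != pure) { pure = -1; break; }
    gsize.push_back(s);
    gpure.push_back(pure);
    gh.push_back(std::move(hist));
    i += s;
  }
  // merge adjacent same-row pure groups into clumps
  std::vector<int> csize;
  std::vector<std::vector<int>> ch;
  int last_pure = -2;
  for (size_t g = 0; g < gsize.size(); ++g) {
    if (gpure[g] >= 0 && gpure[g] == last_pure) {
      csize.back() += gsize[g];
      for (int r = 0; r < q; ++r) ch.back()[r] += gh[g][r];
    } else {
      csize.push_back(gsize[g]);
      ch.push_back(gh[g]);
      last_pure = -2;
    }
    last_pure = (gpure[g] >= 0) ? gpure[g] : -2;
  }
  // coarsen to superclumps
  if (khat > 1 && (int)csize.size() > khat) {
    std::vector<int> ssize;
    std::vector<std::vector<int>> sh;
    double rowsize = (double)n / khat;
    int h = 0, placed = 0;
    int curr = -1;  // force opening a first superclump
    for (size_t c = 0; c < csize.size(); ++c) {
      double t1 = std::fabs((double)h + csize[c] - rowsize);
      double t2 = std::fabs((double)h - rowsize);
      if (curr < 0 || (h != 0 && t1 >= t2 && curr < khat - 1)) {
        ++curr;
        h = 0;
        if (curr > 0) rowsize = (double)(n - placed) / (khat - curr);
        ssize.push_back(0);
        sh.push_back(std::vector<int>(q, 0));
      }
      ssize.back() += csize[c];
      for (int r = 0; r < q; ++r) sh.back()[r] += ch[c][r];
      h += csize[c];
      placed += csize[c];
    }
    csize.swap(ssize);
    ch.swap(sh);
  }
  ClumpTable tab;
  tab.k = (int)csize.size();
  tab.q = q;
  tab.cum.assign(tab.k + 1, 0);
  tab.cumhist.assign((tab.k + 1) * q, 0);
  for (int t = 1; t <= tab.k; ++t) {
    tab.cum[t] = tab.cum[t - 1] + csize[t - 1];
    for (int r = 0; r < q; ++r)
      tab.cumhist[t * q + r] = tab.cumhist[(t - 1) * q + r] + ch[t - 1][r];
  }
  return tab;
}

// Optimal column partitions over clump boundaries.  Fills I[l] (l = 2..lmax)
// with max_{partitions into exactly l columns} H(rows) + [H(cols) - H(cols,rows)];
// entries stay -Inf where k < l.  Objective is additive:
//   H(P) - H(P,Q) = -(1/n) * sum_i n_i * H(rows | column i).
void optimize_axis(const ClumpTable& tab, double hq, int lmax,
                   std::vector<double>& I) {
  const int k = tab.k;
  I.assign(lmax + 1, -std::numeric_limits<double>::infinity());
  if (k < 2) return;
  // segment entropies
  std::vector<double> seg((k + 1) * (k + 1), 0.0);
  for (int s = 0; s <= k; ++s)
    for (int t = s + 1; t <= k; ++t) seg[s * (k + 1) + t] = tab.seg_entropy(s, t);
  std::vector<double> Fprev(k + 1), Fcur(k + 1);
  // l = 2
  for (int t = 2; t <= k; ++t) {
    double best = -std::numeric_limits<double>::infinity();
    double ct = tab.cum[t];
    for (int s = 1; s < t; ++s) {
      double cs = tab.cum[s];
      double v = -(cs / ct) * seg[0 * (k + 1) + s] -
                 ((ct - cs) / ct) * seg[s * (k + 1) + t];
      if (v > best) best = v;
    }
    Fprev[t] = best;
  }
  if (lmax >= 2) I[2] = hq + Fprev[k];
  for (int l = 3; l <= lmax; ++l) {
    if (k < l) break;
    for (int t = l; t <= k; ++t) {
      double best = -std::numeric_limits<double>::infinity();
      double ct = tab.cum[t];
      for (int s = l - 1; s < t; ++s) {
        double cs = tab.cum[s];
        double v = (cs / ct) * Fprev[s] - ((ct - cs) / ct) * seg[s * (k + 1) + t];
        if (v > best) best = v;
      }
      Fcur[t] = best;
    }
    I[l] = hq + Fcur[k];
    std::swap(Fprev, Fcur);
  }
}

double row_entropy(const ClumpTable& tab) {
  return tab.seg_entropy(0, tab.k);
}

}  // namespace

// [[Rcpp::export]]
double mic_approx_cpp(NumericVector x, NumericVector y, double alpha,
                      int clumps) {
  const int n = (int)x.size();
  const double B = std::max(std::pow((double)n, alpha), 4.0);
  double best = 0.0;
  std::vector<int> rowbin;
  for (int pass = 0; pass < 2; ++pass) {
    const NumericVector& a = pass ? y : x;  // optimised axis (columns)
    const NumericVector& b = pass ? x : y;  // equipartitioned axis (rows)
    std::vector<int> ord_a = order_of(a), ord_b = order_of(b);
    const int qmax = (int)std::floor(B / 2.0);
    for (int q = 2; q <= qmax; ++q) {
      const int lmax = (int)std::floor(B / q);
      if (lmax < 2) break;
      int qused = equipartition(b, ord_b, q, rowbin);
      if (qused != q) continue;  // row handled at the coarser q
      ClumpTable tab = build_clumps(a, ord_a, rowbin, q, clumps * lmax);
      double hq = row_entropy(tab);
      std::vector<double> I;
      optimize_axis(tab, hq, lmax, I);
      double run = -std::numeric_limits<double>::infinity();
      for (int l = 2; l <= lmax; ++l) {
        if (I[l] > run) run = I[l];  // empty columns allowed: best over <= l
        if (!std::isfinite(run)) continue;
        double score = run / std::log((double)std::min(l, q));
        if (score > best) best = score;
      }
    }
  }
  return std::min(best, 1.0);
}

// [[Rcpp::export]]
double mic_exact_cpp(NumericVector x, NumericVector y, double alpha) {
  const int n = (int)x.size();
  const double B = std::max(std::pow((double)n, alpha), 4.0);
  const int qenum = (int)std::floor(std::sqrt(B));
  double best = 0.0;
  std::vector<int> rowbin(n);
  for (int pass = 0; pass < 2; ++pass) {
    const NumericVector& e = pass ? x : y;  // enumerated axis (rows)
    const NumericVector& o = pass ? y : x;  // DP-optimised axis (columns)
    std::vector<int> ord_e = order_of(e), ord_o = order_of(o);
    // boundaries between distinct values of e, as positions in sorted order
    std::vector<int> bnd;  // cut after sorted position i (0-based): i in bnd
    for (int i = 0; i + 1 < n; ++i)
      if (e[ord_e[i]] != e[ord_e[i + 1]]) bnd.push_back(i);
    for (int q = 2; q <= qenum; ++q) {
      const int lmax = (int)std::floor(B / q);
      if (lmax < 2) continue;
      if ((int)bnd.size() < q - 1) continue;
      // odometer over combinations of q-1 cuts among bnd
      std::vector<int> cut(q - 1);
      for (int j = 0; j < q - 1; ++j) cut[j] = j;
      const int m = (int)bnd.size();
      while (true) {
        // rows from cuts
        for (int i = 0, r = 0, ci = 0; i < n; ++i) {
          rowbin[ord_e[i]] = r;
          if (ci < q - 1 && i == bnd[cut[ci]]) { ++r; ++ci; }
        }
        // exact DP over value groups of o (no clump merge, no coarsening)
        ClumpTable tab;
        {
          // value groups only: build with rows treated as all-mixed would
          // prevent merging; simplest: temporarily mark merges off by using
          // distinct-value groups directly.
          const int nn = n;
          std::vector<int> gsz;
          std::vector<std::vector<int>> gh;
          int i = 0;
          while (i < nn) {
            int s = 1;
            while (i + s < nn && o[ord_o[i + s]] == o[ord_o[i]]) ++s;
            std::vector<int> hist(q, 0);
            for (int j = 0; j < s; ++j) hist[rowbin[ord_o[i + j]]]++;
            gsz.push_back(s);
            gh.push_back(std::move(hist));
            i += s;
          }
          tab.k = (int)gsz.size();
          tab.q = q;
          tab.cum.assign(tab.k + 1, 0);
          tab.cumhist.assign((tab.k + 1) * q, 0);
          for (int t = 1; t <= tab.k; ++t) {
            tab.cum[t] = tab.cum[t - 1] + gsz[t - 1];
            for (int r = 0; r < q; ++r)
              tab.cumhist[t * q + r] =
                  tab.cumhist[(t - 1) * q + r] + gh[t - 1][r];
          }
        }
        double hq = row_entropy(tab);
        std::vector<double> I;
        optimize_axis(tab, hq, lmax, I);
        double run = -std::numeric_limits<double>::infinity();
        for (int l = 2; l <= lmax; ++l) {
          if (I[l] > run) run = I[l];
          if (!std::isfinite(run)) continue;
          double score = run / std::log((double)std::min(l, q));
          if (score > best) best = score;
        }
        // next combination
        int j = q - 2;
        while (j >= 0 && cut[j] == m - (q - 1) + j) --j;
        if (j < 0) break;
        ++cut[j];
        for (int jj = j + 1; jj < q - 1; ++jj) cut[jj] = cut[jj - 1] + 1;
      }
    }
  }
  return std::min(best, 1.0);
}
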