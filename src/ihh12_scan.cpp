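// Fast whole-genome iHH12 scan. Semantics are identical to the R-level
// ehh12_profile() + ihh12() pair (which serve as the single-core reference
// path): haplotype classes refine site-by-site outward from the core, the
// top two class counts are pooled, and the trapezoid integration stops at
// the interpolated cutoff crossing, the chromosome edge or max_extend.
#include <Rcpp.h>
using namespace Rcpp;

static double ehh12_from_classes(const std::vector<int> &cls, int n,
                                 std::vector<int> &counts) {
  std::fill(counts.begin(), counts.end(), 0);
  for (int h = 0; h < n; ++h) counts[cls[h]]++;
  int top1 = 0, top2 = 0;
  double sum_rest = 0.0;
  for (int c = 0; c < n; ++c) {
    int k = counts[c];
    if (k == 0) continue;
    if (k > top1) {
      sum_rest += 0.5 * top2 * (top2 - 1);
      top2 = top1;
      top1 = k;
    } else if (k > top2) {
      sum_rest += 0.5 * top2 * (top2 - 1);
      top2 = k;
    } else {
      sum_rest += 0.5 * k * (k - 1);
    }
  }
  double pooled = 0.5 * (double)(top1 + top2) * (top1 + top2 - 1);
  return (pooled + sum_rest) / (0.5 * (double)n * (n - 1));
}

// [[Rcpp::export]]
NumericVector ihh12_scan_cpp(IntegerMatrix H, NumericVector pos,
                             IntegerVector chrom_id, double cutoff,
                             double max_extend) {
  int S = H.nrow(), n = H.ncol();
  NumericVector out(S);
  std::vector<int> cls(n), nxt(n), counts(n), remap(2 * n + 2);
  for (int core = 0; core < S; ++core) {
    double area = 0.0;
    for (int dir = -1; dir <= 1; dir += 2) {
      for (int h = 0; h < n; ++h) cls[h] = H(core, h);
      double prev_e = 1.0, prev_d = 0.0;
      for (int j = core + dir; j >= 0 && j < S; j += dir) {
        if (chrom_id[j] != chrom_id[core]) break;
        double d = pos[j] > pos[core] ? pos[j] - pos[core]
                                      : pos[core] - pos[j];
        if (d > max_extend) break;
        std::fill(remap.begin(), remap.end(), -1);
        int next_id = 0;
        for (int h = 0; h < n; ++h) {
          int key = cls[h] * 2 + H(j, h);
          if (remap[key] < 0) remap[key] = next_id++;
          nxt[h] = remap[key];
        }
        std::swap(cls, nxt);
        double e = ehh12_from_classes(cls, n, counts);
        if (e >= cutoff) {
          area += 0.5 * (prev_e + e) * (d - prev_d);
          prev_e = e;
          prev_d = d;
        } else {
          double x = prev_d + (d - prev_d) * (prev_e - cutoff) / (prev_e - e);
          area += 0.5 * (prev_e + cutoff) * (x - prev_d);
          break;
        }
      }
    }
    out[core] = area;
  }
  return out;
}
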