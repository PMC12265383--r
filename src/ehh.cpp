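#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Extended haplotype homozygosity decay by partition refinement.
//
// H:          2N x V allele matrix (0/1, NA = missing)
// rows:       0-based haplotype row indices to track
// cols:       0-based column indices to visit, ordered outward from the core
// init_class: initial class label per tracked haplotype (core partition)
// pool2:      pool the two largest extended-haplotype classes (EHH12)
// cutoff:     stop after the first value below this threshold
//
// The denominator is C(n0, 2) with n0 the initially tracked haplotype
// count; haplotypes are dropped (not renormalized) at their first missing
// call on this side. Returns one homozygosity value per visited column,
// truncated after the first value < cutoff.
// [[Rcpp::export]]
NumericVector ehh_decay_cpp(IntegerMatrix H, IntegerVector rows,
                            IntegerVector cols, IntegerVector init_class,
                            bool pool2, double cutoff) {
  int n0 = rows.size();
  std::vector<int> cls(init_class.begin(), init_class.end());
  std::vector<bool> active(n0, true);
  double denom = 0.5 * n0 * (n0 - 1);
  std::vector<double> out;
  out.reserve(cols.size());

  for (int c = 0; c < cols.size(); ++c) {
    int col = cols[c];
    std::unordered_map<long long, int> remap;
    std::unordered_map<int, int> counts;
    int next_id = 0;
    for (int i = 0; i < n0; ++i) {
      if (!active[i]) continue;
      int a = H(rows[i], col);
      if (a == NA_INTEGER) { active[i] = false; continue; }
      long long key = (long long)cls[i] * 3LL + a;
      auto it = remap.find(key);
      int id;
      if (it == remap.end()) { id = next_id++; remap[key] = id; }
      else id = it->second;
      cls[i] = id;
      counts[id] += 1;
    }
    double hom = 0.0;
    int top1 = 0, top2 = 0;
    for (auto& kv : counts) {
      double n = kv.second;
      hom += 0.5 * n * (n - 1);
      if (kv.second > top1) { top2 = top1; top1 = kv.second; }
      else if (kv.second > top2) top2 = kv.second;
    }
    if (pool2) hom += (double)top1 * top2;
    double val = denom > 0 ? hom / denom : 0.0;
    out.push_back(val);
    if (val < cutoff) break;
  }
  return wrap(out);
}
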