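// Shadow contact map: native atom pairs within a distance cutoff whose
// straight line of sight is not occluded by a third atom sphere.
#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline long long pkey(int i, int j, int n) {
  return (long long)std::min(i, j) * n + std::max(i, j);
}

// xyz in nm; excl are 1-based pairs (graph distance <= 2); classcode:
// 0 = protein, 1 = nucleic, 2 = other. Returns (i, j, r0_nm) with i < j.
// [[Rcpp::export]]
NumericMatrix shadow_pairs_cpp(NumericMatrix xyz, double cutoff, double rshadow,
                               IntegerVector chain_idx, IntegerVector resno,
                               IntegerVector classcode, IntegerMatrix excl,
                               int minsep_prot, int minsep_nuc) {
  const int n = xyz.nrow();
  std::unordered_set<long long> ex;
  for (int r = 0; r < excl.nrow(); ++r)
    ex.insert(pkey(excl(r, 0) - 1, excl(r, 1) - 1, n));

  const double occ = 2.0 * rshadow;       // shadow_radius + light radius
  const double nbr_cut = cutoff + occ;    // occluder candidate radius
  const double cut2 = cutoff * cutoff, nbr2 = nbr_cut * nbr_cut;

  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i,0)-xyz(j,0), dy = xyz(i,1)-xyz(j,1), dz = xyz(i,2)-xyz(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < nbr2) { nbr[i].push_back(j); nbr[j].push_back(i); }
    }
  }

  std::vector<double> oi, oj, orr;
  for (int i = 0; i < n; ++i) {
    for (size_t q = 0; q < nbr[i].size(); ++q) {
      int j = nbr[i][q];
      if (j <= i) continue;
      double dx = xyz(j,0)-xyz(i,0), dy = xyz(j,1)-xyz(i,1), dz = xyz(j,2)-xyz(i,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > cut2) continue;
      if (d2 < 1e-12)
        stop("degenerate coordinates: atoms %d and %d coincide", i + 1, j + 1);
      if (ex.count(pkey(i, j, n))) continue;
      // sequence-separation rule per category
      if (chain_idx[i] == chain_idx[j]) {
        int sep = std::abs(resno[i] - resno[j]);
        bool prot = classcode[i] == 0 && classcode[j] == 0;
        int need = prot ? minsep_prot : minsep_nuc;
        if (sep < need) continue;
      }
      // occlusion by any third atom sphere near the segment
      double d = std::sqrt(d2);
      bool blocked = false;
      for (size_t w = 0; w < nbr[i].size() && !blocked; ++w) {
        int k = nbr[i][w];
        if (k == j) continue;
        double vx = xyz(k,0)-xyz(i,0), vy = xyz(k,1)-xyz(i,1), vz = xyz(k,2)-xyz(i,2);
        double t = (vx*dx + vy*dy + vz*dz) / d2;
        if (t <= 0.0 || t >= 1.0) continue;   // strictly between projections
        double px = vx - t*dx, py = vy - t*dy, pz = vz - t*dz;
        if (px*px + py*py + pz*pz < occ*occ) blocked = true;
      }
      if (!blocked) { oi.push_back(i + 1); oj.push_back(j + 1); orr.push_back(d); }
    }
  }
  NumericMatrix out(oi.size(), 3);
  for (size_t r = 0; r < oi.size(); ++r) {
    out(r, 0) = oi[r]; out(r, 1) = oj[r]; out(r, 2) = orr[r];
  }
  return out;
}
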