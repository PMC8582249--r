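#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Deterministic, seed-free quadrature point set on the unit sphere
// (golden-section spiral).  The same point set is reused for every atom,
// which makes SASA exactly rotation-invariant when the frame is rotated
// together with the point set and reproducible across platforms.
// [[Rcpp::export]]
NumericMatrix golden_spiral_points(int n) {
  if (n < 1) stop("need at least one quadrature point");
  NumericMatrix pts(n, 3);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n; ++i) {
    // z strictly inside (-1, 1) so every point is well defined
    double z = 1.0 - (2.0 * i + 1.0) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = golden * i;
    pts(i, 0) = r * std::cos(phi);
    pts(i, 1) = r * std::sin(phi);
    pts(i, 2) = z;
  }
  return pts;
}

// Shrake-Rupley solvent-accessible surface area, one value per atom.
// Each atom is inflated by the probe radius; the fraction of quadrature
// points on its inflated sphere not inside any neighbour's inflated
// sphere gives the accessible fraction.  Neighbour search is exact
// (direct enumeration with the analytic contact cutoff), so results do
// not depend on any binning approximation.
// [[Rcpp::export]]
NumericVector sasa_shrake_rupley(NumericMatrix xyz, NumericVector radii,
                                 double probe, int npoints) {
  const int n = xyz.nrow();
  if (radii.size() != n) stop("radii length must match atom count");
  if (probe < 0) stop("probe radius must be non-negative");
  NumericVector area(n);
  if (n == 0) return area;
  for (int i = 0; i < n; ++i) {
    if (!R_finite(radii[i]) || radii[i] <= 0)
      stop("all atoms need a positive finite radius");
  }
  NumericMatrix pts = golden_spiral_points(npoints);

  std::vector<double> ext(n);
  for (int i = 0; i < n; ++i) ext[i] = radii[i] + probe;

  std::vector<int> nb;
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double Ri = ext[i];
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double cut = Ri + ext[j];
      double dx = xyz(j, 0) - xyz(i, 0);
      double dy = xyz(j, 1) - xyz(i, 1);
      double dz = xyz(j, 2) - xyz(i, 2);
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < npoints; ++k) {
      double px = xyz(i, 0) + Ri * pts(k, 0);
      double py = xyz(i, 1) + Ri * pts(k, 1);
      double pz = xyz(i, 2) + Ri * pts(k, 2);
      bool buried = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = px - xyz(j, 0);
        double dy = py - xyz(j, 1);
        double dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < ext[j] * ext[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)npoints;
  }
  return area;
}

// Minimum heavy-atom distance between two coordinate blocks; helper for
// residue-residue contact tables (kept in C++ because it sits inside a
// per-frame, per-residue-pair loop).
// [[Rcpp::export]]
double min_pair_distance(NumericMatrix a, NumericMatrix b) {
  double best = R_PosInf;
  for (int i = 0; i < a.nrow(); ++i) {
    for (int j = 0; j < b.nrow(); ++j) {
      double dx = a(i, 0) - b(j, 0);
      double dy = a(i, 1) - b(j, 1);
      double dz = a(i, 2) - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// All cross-binder residue pairs whose minimum heavy-atom distance is
// within `cutoff`.  `resA`/`resB` give a residue index (1-based) per
// atom; returns a matrix with columns: resA id, resB id, min distance.
// [[Rcpp::export]]
NumericMatrix residue_min_distances(NumericMatrix xyzA, IntegerVector resA,
                                    NumericMatrix xyzB, IntegerVector resB,
                                    double cutoff) {
  int nResA = 0, nResB = 0;
  for (int i = 0; i < resA.size(); ++i) nResA = std::max(nResA, resA[i]);
  for (int i = 0; i < resB.size(); ++i) nResB = std::max(nResB, resB[i]);
  std::vector<double> best((size_t)nResA * nResB, R_PosInf);
  for (int i = 0; i < xyzA.nrow(); ++i) {
    for (int j = 0; j < xyzB.nrow(); ++j) {
      double dx = xyzA(i, 0) - xyzB(j, 0);
      double dy = xyzA(i, 1) - xyzB(j, 1);
      double dz = xyzA(i, 2) - xyzB(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      size_t idx = (size_t)(resA[i] - 1) * nResB + (resB[j] - 1);
      if (d2 < best[idx]) best[idx] = d2;
    }
  }
  int hits = 0;
  double cut2 = cutoff * cutoff;
  for (size_t k = 0; k < best.size(); ++k)
    if (best[k] <= cut2) ++hits;
  NumericMatrix out(hits, 3);
  int row = 0;
  for (int a = 0; a < nResA; ++a) {
    for (int b = 0; b < nResB; ++b) {
      double d2 = best[(size_t)a * nResB + b];
      if (d2 <= cut2) {
        out(row, 0) = a + 1;
        out(row, 1) = b + 1;
        out(row, 2) = std::sqrt(d2);
        ++row;
      }
    }
  }
  return out;
}

// ---- per-trajectory descriptor kernel --------------------------------------
// The per-frame BSA/HBS loop of a trajectory runs here so the 100-frame
// analysis of a pose costs milliseconds rather than seconds.  Semantics
// mirror the single-structure interface analysis exactly (same thresholds,
// same complex = union-of-binders convention); a test pins the two paths
// to identical results.

static void sasa_into(const std::vector<double> &x, const std::vector<double> &y,
                      const std::vector<double> &z, const std::vector<double> &ext,
                      const NumericMatrix &pts, std::vector<double> &area) {
  const int n = (int)x.size();
  const int npoints = pts.nrow();
  area.assign(n, 0.0);
  std::vector<int> nb;
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double Ri = ext[i];
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double cut = Ri + ext[j];
      double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < npoints; ++k) {
      double px = x[i] + Ri * pts(k, 0);
      double py = y[i] + Ri * pts(k, 1);
      double pz = z[i] + Ri * pts(k, 2);
      bool buried = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = px - x[j], dy = py - y[j], dz = pz - z[j];
        if (dx * dx + dy * dy + dz * dz < ext[j] * ext[j]) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)npoints;
  }
}

// Per-frame BSA and HBS over a trajectory.  `idxA`/`idxB` are 1-based
// atom indices of the two binders; `resFacA`/`resFacB` number the
// residues within each binder (1-based, parallel to idxA/idxB);
// `hydroA`/`hydroB` flag atoms whose parent residue is hydrophobic.
// [[Rcpp::export]]
DataFrame traj_interface_descriptors(List frames, NumericVector radii,
                                     IntegerVector idxA, IntegerVector idxB,
                                     IntegerVector resFacA, IntegerVector resFacB,
                                     LogicalVector hydroA, LogicalVector hydroB,
                                     double probe, int npoints,
                                     double res_thresh, double atom_eps) {
  const int nf = frames.size();
  const int nA = idxA.size(), nB = idxB.size();
  NumericMatrix pts = golden_spiral_points(npoints);
  int nResA = 0, nResB = 0;
  for (int i = 0; i < nA; ++i) nResA = std::max(nResA, resFacA[i]);
  for (int i = 0; i < nB; ++i) nResB = std::max(nResB, resFacB[i]);

  NumericVector bsa(nf);
  IntegerVector hbs(nf);
  std::vector<double> xA(nA), yA(nA), zA(nA), extA(nA);
  std::vector<double> xB(nB), yB(nB), zB(nB), extB(nB);
  std::vector<double> xC(nA + nB), yC(nA + nB), zC(nA + nB), extC(nA + nB);
  std::vector<double> aA, aB, aC;
  for (int i = 0; i < nA; ++i) extA[i] = radii[idxA[i] - 1] + probe;
  for (int i = 0; i < nB; ++i) extB[i] = radii[idxB[i] - 1] + probe;
  for (int i = 0; i < nA; ++i) extC[i] = extA[i];
  for (int i = 0; i < nB; ++i) extC[nA + i] = extB[i];

  for (int f = 0; f < nf; ++f) {
    NumericMatrix xyz = frames[f];
    for (int i = 0; i < nA; ++i) {
      int a = idxA[i] - 1;
      xA[i] = xyz(a, 0); yA[i] = xyz(a, 1); zA[i] = xyz(a, 2);
      xC[i] = xA[i]; yC[i] = yA[i]; zC[i] = zA[i];
    }
    for (int i = 0; i < nB; ++i) {
      int b = idxB[i] - 1;
      xB[i] = xyz(b, 0); yB[i] = xyz(b, 1); zB[i] = xyz(b, 2);
      xC[nA + i] = xB[i]; yC[nA + i] = yB[i]; zC[nA + i] = zB[i];
    }
    sasa_into(xA, yA, zA, extA, pts, aA);
    sasa_into(xB, yB, zB, extB, pts, aB);
    sasa_into(xC, yC, zC, extC, pts, aC);
    double totA = 0, totB = 0, totC = 0;
    for (int i = 0; i < nA; ++i) totA += aA[i];
    for (int i = 0; i < nB; ++i) totB += aB[i];
    for (size_t i = 0; i < aC.size(); ++i) totC += aC[i];
    double b_ = totA + totB - totC;
    if (b_ < 0 && std::fabs(b_) < 1e-6) b_ = 0;
    bsa[f] = b_;

    std::vector<double> dResA(nResA, 0.0), dResB(nResB, 0.0);
    for (int i = 0; i < nA; ++i) dResA[resFacA[i] - 1] += aA[i] - aC[i];
    for (int i = 0; i < nB; ++i) dResB[resFacB[i] - 1] += aB[i] - aC[nA + i];
    int count = 0;
    for (int i = 0; i < nA; ++i) {
      if (hydroA[i] && dResA[resFacA[i] - 1] > res_thresh &&
          (aA[i] - aC[i]) > atom_eps) ++count;
    }
    for (int i = 0; i < nB; ++i) {
      if (hydroB[i] && dResB[resFacB[i] - 1] > res_thresh &&
          (aB[i] - aC[nA + i]) > atom_eps) ++count;
    }
    hbs[f] = count;
  }
  return DataFrame::create(_["bsa"] = bsa, _["hbs"] = hbs);
}
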