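#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Minimum-image displacement along one axis; L <= 0 disables periodicity.
static inline double min_image(double d, double L) {
  if (L > 0.0) d -= L * std::round(d / L);
  return d;
}

// Cell-list pair search between two atom groups under an orthorhombic box.
// xyz: n x 3 coordinates (Angstrom); box: length-3 (non-positive entry =>
// no periodicity on that axis); idx_a / idx_b: 1-based atom indices.
// Returns a list with 1-based indices ai, bi (into the full atom table)
// and the pair distance, for all pairs with d <= cutoff (closed boundary).
// [[Rcpp::export]]
List pairs_within_cutoff_cpp(NumericMatrix xyz, NumericVector box,
                             IntegerVector idx_a, IntegerVector idx_b,
                             double cutoff) {
  const int na = idx_a.size(), nb = idx_b.size();
  const double cut2 = cutoff * cutoff;
  double L[3];
  int ncell[3];
  for (int k = 0; k < 3; ++k) {
    L[k] = box[k];
    if (L[k] > 0.0) {
      ncell[k] = std::max(1, (int)std::floor(L[k] / cutoff));
      if (ncell[k] > 64) ncell[k] = 64;
    } else {
      ncell[k] = 1;
    }
  }

  // Bin group-b atoms into cells (wrapped coordinates when periodic).
  // Non-periodic axes use a single cell: the double loop over that axis
  // degrades gracefully to brute force, which is fine for desk-scale use.
  std::vector<double> bL(3);
  double lo[3] = {0, 0, 0};
  for (int k = 0; k < 3; ++k) {
    if (L[k] > 0.0) {
      bL[k] = L[k] / ncell[k];
    } else {
      // bounding interval of group b
      double mn = R_PosInf, mx = R_NegInf;
      for (int j = 0; j < nb; ++j) {
        double v = xyz(idx_b[j] - 1, k);
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      if (!R_FINITE(mn)) { mn = 0; mx = 1; }
      lo[k] = mn;
      int nc = std::max(1, (int)std::floor((mx - mn) / cutoff));
      if (nc > 64) nc = 64;
      ncell[k] = nc;
      bL[k] = (mx - mn) / nc;
      if (bL[k] <= 0) bL[k] = 1.0;
    }
  }
  const int ntot = ncell[0] * ncell[1] * ncell[2];
  std::vector<std::vector<int> > cells(ntot);
  auto cell_of = [&](double x, int k) -> int {
    int c;
    if (L[k] > 0.0) {
      double w = x - L[k] * std::floor(x / L[k]);
      c = (int)(w / bL[k]);
    } else {
      c = (int)((x - lo[k]) / bL[k]);
    }
    if (c < 0) c = 0;
    if (c >= ncell[k]) c = ncell[k] - 1;
    return c;
  };
  for (int j = 0; j < nb; ++j) {
    int r = idx_b[j] - 1;
    int cx = cell_of(xyz(r, 0), 0), cy = cell_of(xyz(r, 1), 1),
        cz = cell_of(xyz(r, 2), 2);
    cells[(cz * ncell[1] + cy) * ncell[0] + cx].push_back(j);
  }

  std::vector<int> out_a, out_b;
  std::vector<double> out_d;
  std::vector<int> visit;
  visit.reserve(27);
  for (int i = 0; i < na; ++i) {
    int ra = idx_a[i] - 1;
    double ax = xyz(ra, 0), ay = xyz(ra, 1), az = xyz(ra, 2);
    int c0[3] = {cell_of(ax, 0), cell_of(ay, 1), cell_of(az, 2)};
    visit.clear();
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int cc[3] = {c0[0] + dx, c0[1] + dy, c0[2] + dz};
          bool ok = true;
          for (int k = 0; k < 3; ++k) {
            if (L[k] > 0.0) {
              cc[k] = (cc[k] + ncell[k]) % ncell[k];
            } else if (cc[k] < 0 || cc[k] >= ncell[k]) {
              ok = false;
            }
          }
          if (!ok) continue;
          int id = (cc[2] * ncell[1] + cc[1]) * ncell[0] + cc[0];
          if (std::find(visit.begin(), visit.end(), id) == visit.end())
            visit.push_back(id);
        }
    for (size_t v = 0; v < visit.size(); ++v) {
      const std::vector<int>& cell = cells[visit[v]];
      for (size_t u = 0; u < cell.size(); ++u) {
        int rb = idx_b[cell[u]] - 1;
        double dx = min_image(ax - xyz(rb, 0), L[0]);
        double dy = min_image(ay - xyz(rb, 1), L[1]);
        double dz = min_image(az - xyz(rb, 2), L[2]);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= cut2) {
          out_a.push_back(ra + 1);
          out_b.push_back(rb + 1);
          out_d.push_back(std::sqrt(d2));
        }
      }
    }
  }
  return List::create(_["ai"] = wrap(out_a), _["bi"] = wrap(out_b),
                      _["dist"] = wrap(out_d));
}

// Shrake-Rupley SASA for atoms `subset` (1-based) with every atom in the
// system acting as an occluder.  sphere_pts: npts x 3 unit vectors
// (deterministic lattice supplied from R).  No periodic images: the groups
// analysed here sit well inside the box.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii,
                       IntegerVector subset, double probe,
                       NumericMatrix sphere_pts) {
  const int n = xyz.nrow(), ns = subset.size(), npts = sphere_pts.nrow();
  NumericVector area(ns);
  double rmax = 0.0;
  for (int j = 0; j < n; ++j) rmax = std::max(rmax, radii[j]);
  std::vector<int> nb;
  std::vector<double> nbx, nby, nbz, nbr2;
  for (int s = 0; s < ns; ++s) {
    int i = subset[s] - 1;
    double Ri = radii[i] + probe;
    double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    nb.clear(); nbx.clear(); nby.clear(); nbz.clear(); nbr2.clear();
    double reach = Ri + rmax + probe;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xi - xyz(j, 0), dy = yi - xyz(j, 1), dz = zi - xyz(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double rj = radii[j] + probe;
      if (d2 < (Ri + rj) * (Ri + rj) && d2 <= reach * reach) {
        nb.push_back(j);
        nbx.push_back(xyz(j, 0)); nby.push_back(xyz(j, 1));
        nbz.push_back(xyz(j, 2)); nbr2.push_back(rj * rj);
      }
    }
    int acc = 0;
    const int nn = (int)nb.size();
    for (int p = 0; p < npts; ++p) {
      double px = xi + Ri * sphere_pts(p, 0);
      double py = yi + Ri * sphere_pts(p, 1);
      double pz = zi + Ri * sphere_pts(p, 2);
      bool free_pt = true;
      for (int q = 0; q < nn; ++q) {
        double dx = px - nbx[q], dy = py - nby[q], dz = pz - nbz[q];
        if (dx * dx + dy * dy + dz * dz < nbr2[q]) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[s] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)npts;
  }
  return area;
}
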