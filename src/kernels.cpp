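#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// minimum-image separation along one axis of an orthorhombic box
static inline double mi(double d, double L) {
  d -= L * std::round(d / L);
  return d;
}

static inline double mi_dist2(const double* x, const double* y, const double* z,
                              int i, int j, double Lx, double Ly, double Lz) {
  double dx = mi(x[i] - x[j], Lx);
  double dy = mi(y[i] - y[j], Ly);
  double dz = mi(z[i] - z[j], Lz);
  return dx * dx + dy * dy + dz * dz;
}

// Pair-distance histogram under the minimum-image convention.
// Returns counts of unordered pairs with distance in [k*bin, (k+1)*bin),
// for distances < r_max.
// [[Rcpp::export(name = ".pair_histogram_cpp")]]
IntegerVector pair_histogram_cpp(NumericVector x, NumericVector y, NumericVector z,
                                 NumericVector box, double bin_width, double r_max) {
  const int n = x.size();
  const int nbins = (int)std::ceil(r_max / bin_width);
  IntegerVector counts(nbins);
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double r2max = r_max * r_max;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d2 = mi_dist2(x.begin(), y.begin(), z.begin(), i, j, Lx, Ly, Lz);
      if (d2 < r2max) {
        int k = (int)(std::sqrt(d2) / bin_width);
        if (k >= 0 && k < nbins) counts[k]++;
      }
    }
  }
  return counts;
}

// Minimum over all minimum-image pair distances (hard-core check).
// [[Rcpp::export(name = ".min_pair_distance_cpp")]]
double min_pair_distance_cpp(NumericVector x, NumericVector y, NumericVector z,
                             NumericVector box) {
  const int n = x.size();
  double best = R_PosInf;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d2 = mi_dist2(x.begin(), y.begin(), z.begin(), i, j, box[0], box[1], box[2]);
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}

// Hard-sphere configuration: random sequential insertion followed by
// Metropolis relaxation sweeps. Uses the R RNG so seeding is controlled from R.
// Returns an n x 3 matrix, or throws if placement fails within the attempt budget.
// [[Rcpp::export(name = ".hard_sphere_cpp")]]
NumericMatrix hard_sphere_cpp(int n, NumericVector box, double radius,
                              int n_sweeps, double max_step, int max_attempts) {
  RNGScope scope;
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double dmin = 2.0 * radius, d2min = dmin * dmin;
  std::vector<double> x(n), y(n), z(n);
  int placed = 0;
  long attempts = 0;
  while (placed < n) {
    if (attempts++ > (long)max_attempts)
      stop("placement failure: could not insert %d hard spheres within %d attempts",
           n, max_attempts);
    double px = unif_rand() * Lx, py = unif_rand() * Ly, pz = unif_rand() * Lz;
    bool ok = true;
    for (int j = 0; j < placed; ++j) {
      double dx = mi(px - x[j], Lx), dy = mi(py - y[j], Ly), dz = mi(pz - z[j], Lz);
      if (dx * dx + dy * dy + dz * dz < d2min) { ok = false; break; }
    }
    if (ok) { x[placed] = px; y[placed] = py; z[placed] = pz; ++placed; }
  }
  // Metropolis relaxation: random single-particle displacements, rejected on overlap
  for (int s = 0; s < n_sweeps; ++s) {
    for (int i = 0; i < n; ++i) {
      double px = x[i] + (unif_rand() - 0.5) * 2.0 * max_step;
      double py = y[i] + (unif_rand() - 0.5) * 2.0 * max_step;
      double pz = z[i] + (unif_rand() - 0.5) * 2.0 * max_step;
      px -= Lx * std::floor(px / Lx);
      py -= Ly * std::floor(py / Ly);
      pz -= Lz * std::floor(pz / Lz);
      bool ok = true;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double dx = mi(px - x[j], Lx), dy = mi(py - y[j], Ly), dz = mi(pz - z[j], Lz);
        if (dx * dx + dy * dy + dz * dz < d2min) { ok = false; break; }
      }
      if (ok) { x[i] = px; y[i] = py; z[i] = pz; }
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i]; }
  return out;
}

// Per-particle sorted neighbor distances for the local structure index.
// For particle i: all minimum-image distances are sorted ascending; n_i is the
// count with r < cutoff; the first neighbor beyond the cutoff is also needed.
// Returns a list with n_neighbors, lsi (NA when the molecule must be skipped),
// and r_next (first distance beyond the cutoff).
// [[Rcpp::export(name = ".lsi_cpp")]]
List lsi_cpp(NumericVector x, NumericVector y, NumericVector z,
             NumericVector box, double cutoff) {
  const int n = x.size();
  const double half_min_box = 0.5 * std::min(box[0], std::min(box[1], box[2]));
  IntegerVector n_nb(n);
  NumericVector lsi(n), rnext(n);
  std::vector<double> d(n - 1);
  for (int i = 0; i < n; ++i) {
    int k = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      d[k++] = std::sqrt(mi_dist2(x.begin(), y.begin(), z.begin(), i, j,
                                  box[0], box[1], box[2]));
    }
    std::sort(d.begin(), d.end());
    int ni = 0;
    while (ni < n - 1 && d[ni] < cutoff) ++ni;
    n_nb[i] = ni;
    if (ni < 1 || ni >= n - 1 || d[ni] > half_min_box) {
      // no neighbor inside the cutoff, or the first neighbor beyond it is
      // missing / outside the minimum-image sphere: skip this molecule
      lsi[i] = NA_REAL;
      rnext[i] = (ni < n - 1) ? d[ni] : NA_REAL;
      continue;
    }
    rnext[i] = d[ni];
    // gaps between successive sorted distances, j = 1..n_i (last gap spans the cutoff)
    double mean = 0.0;
    for (int j = 0; j < ni; ++j) mean += d[j + 1] - d[j];
    mean /= ni;
    double v = 0.0;
    for (int j = 0; j < ni; ++j) {
      double g = d[j + 1] - d[j] - mean;
      v += g * g;
    }
    lsi[i] = v / ni;
  }
  return List::create(_["n_neighbors"] = n_nb, _["lsi"] = lsi, _["r_next"] = rnext);
}
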