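#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Debye-formula scattering intensity for point scatterers with a shared
// Gaussian form-factor shape: I(q) = g(q)^2 * sum_ab F_a F_b sinc(q r_ab).
// coords: n x 3, f0: length n electron counts, q: grid, rbead: bead radius.
// [[Rcpp::export(name = ".debye_intensity")]]
NumericVector debye_intensity_cpp(NumericMatrix coords, NumericVector f0,
                                  NumericVector q, double rbead) {
  int n = coords.nrow(), nq = q.size();
  std::vector<double> d;
  std::vector<double> ff;
  d.reserve((size_t)n * (n - 1) / 2);
  ff.reserve(d.capacity());
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      double dx = coords(a, 0) - coords(b, 0);
      double dy = coords(a, 1) - coords(b, 1);
      double dz = coords(a, 2) - coords(b, 2);
      d.push_back(std::sqrt(dx * dx + dy * dy + dz * dz));
      ff.push_back(f0[a] * f0[b]);
    }
  }
  double self = 0.0;
  for (int a = 0; a < n; ++a) self += f0[a] * f0[a];
  NumericVector I(nq);
  // uniform grids take a fast path replacing per-point sin() with the
  // three-term sine recurrence sin((k+1)h) = 2 cos(h) sin(kh) - sin((k-1)h)
  bool uniform = nq >= 3;
  double dq = (nq >= 2) ? q[1] - q[0] : 0.0;
  for (int k = 2; uniform && k < nq; ++k) {
    if (std::fabs((q[k] - q[k - 1]) - dq) > 1e-9 * std::max(1.0, std::fabs(dq)))
      uniform = false;
  }
  if (uniform) {
    std::vector<double> acc(nq, 0.0);
    for (size_t p = 0; p < d.size(); ++p) {
      double dd = d[p], w = ff[p];
      if (dd < 1e-12) {
        for (int k = 0; k < nq; ++k) acc[k] += w;
        continue;
      }
      double c2 = 2.0 * std::cos(dq * dd);
      double x0 = q[0] * dd, x1 = q[1] * dd;
      double sm2 = std::sin(x0), sm1 = std::sin(x1);
      acc[0] += w * ((x0 < 1e-9) ? 1.0 : sm2 / x0);
      acc[1] += w * ((x1 < 1e-9) ? 1.0 : sm1 / x1);
      for (int k = 2; k < nq; ++k) {
        double s = c2 * sm1 - sm2;
        sm2 = sm1; sm1 = s;
        double x = q[k] * dd;
        acc[k] += w * ((x < 1e-9) ? 1.0 : s / x);
      }
    }
    for (int k = 0; k < nq; ++k) {
      double g = std::exp(-q[k] * q[k] * rbead * rbead / 2.0);
      I[k] = g * g * (self + 2.0 * acc[k]);
    }
    return I;
  }
  for (int k = 0; k < nq; ++k) {
    double qk = q[k];
    double g = std::exp(-qk * qk * rbead * rbead / 2.0);
    double s = self;
    for (size_t p = 0; p < d.size(); ++p) {
      double x = qk * d[p];
      double sinc = (x < 1e-9) ? 1.0 : std::sin(x) / x;
      s += 2.0 * ff[p] * sinc;
    }
    I[k] = g * g * s;
  }
  return I;
}

// Knowledge-based potential energy: sum of table lookups over all atom
// pairs of non-adjacent residues (|resid difference| >= 2) within range.
// coords: m x 3 (stacked atoms), atype: 1..3 atom type, resid: residue id,
// table: 6 x nbins (unordered type-pair rows), bw: bin width, maxd: range.
// [[Rcpp::export(name = ".pair_potential_energy")]]
double pair_potential_energy_cpp(NumericMatrix coords, IntegerVector atype,
                                 IntegerVector resid, NumericMatrix table,
                                 double bw, double maxd) {
  int m = coords.nrow(), nb = table.ncol();
  double e = 0.0, maxd2 = maxd * maxd;
  for (int a = 0; a < m; ++a) {
    for (int b = a + 1; b < m; ++b) {
      int dr = resid[a] - resid[b];
      if (dr < 0) dr = -dr;
      if (dr < 2) continue;
      double dx = coords(a, 0) - coords(b, 0);
      double dy = coords(a, 1) - coords(b, 1);
      double dz = coords(a, 2) - coords(b, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= maxd2) continue;
      int t1 = atype[a], t2 = atype[b];
      if (t1 > t2) { int tmp = t1; t1 = t2; t2 = tmp; }
      // unordered pair row index for types in 1..3
      int row = (t1 - 1) * 3 - ((t1 - 1) * (t1 - 2)) / 2 + (t2 - t1);
      int bin = (int)(std::sqrt(d2) / bw);
      if (bin >= nb) continue;
      e += table(row, bin);
    }
  }
  return e;
}

// Glycosidic-nitrogen clash count via a spatial grid (cell lists).
// n_xyz: n x 3 glycosidic N coordinates; resid: 1-based residue numbers
// (rows may be a subset of a chain); excl_i/excl_j: residue-number pairs
// excluded from counting (base-paired residues); sequence neighbours
// (|resid difference| <= 1) are always excluded. Strict "< cutoff".
// [[Rcpp::export(name = ".count_clashes_grid")]]
int count_clashes_grid_cpp(NumericMatrix n_xyz, IntegerVector resid,
                           IntegerVector excl_i, IntegerVector excl_j,
                           double cutoff) {
  int n = n_xyz.nrow();
  if (n < 2) return 0;
  double c2 = cutoff * cutoff;
  long long NR = 0;
  for (int i = 0; i < n; ++i) NR = std::max(NR, (long long)resid[i]);
  NR += 2;
  std::unordered_map<long long, bool> excl;
  for (int k = 0; k < excl_i.size(); ++k) {
    long long a = excl_i[k], b = excl_j[k];
    if (a > b) std::swap(a, b);
    excl[a * NR + b] = true;
  }
  // grid with cell size = cutoff
  double minx = n_xyz(0, 0), miny = n_xyz(0, 1), minz = n_xyz(0, 2);
  for (int i = 1; i < n; ++i) {
    minx = std::min(minx, n_xyz(i, 0));
    miny = std::min(miny, n_xyz(i, 1));
    minz = std::min(minz, n_xyz(i, 2));
  }
  std::unordered_map<long long, std::vector<int> > cells;
  std::vector<long long> cx(n), cy(n), cz(n);
  const long long K = 1 << 20;
  for (int i = 0; i < n; ++i) {
    cx[i] = (long long)((n_xyz(i, 0) - minx) / cutoff);
    cy[i] = (long long)((n_xyz(i, 1) - miny) / cutoff);
    cz[i] = (long long)((n_xyz(i, 2) - minz) / cutoff);
    cells[(cx[i] * K + cy[i]) * K + cz[i]].push_back(i);
  }
  int count = 0;
  for (int i = 0; i < n; ++i) {
    for (long long dx = -1; dx <= 1; ++dx) {
      for (long long dy = -1; dy <= 1; ++dy) {
        for (long long dz = -1; dz <= 1; ++dz) {
          long long key = ((cx[i] + dx) * K + cy[i] + dy) * K + cz[i] + dz;
          std::unordered_map<long long, std::vector<int> >::iterator it =
              cells.find(key);
          if (it == cells.end()) continue;
          const std::vector<int> &v = it->second;
          for (size_t t = 0; t < v.size(); ++t) {
            int j = v[t];
            if (j <= i) continue;
            long long ra = resid[i], rb = resid[j];
            if (ra > rb) std::swap(ra, rb);
            if (rb - ra <= 1) continue;
            double ddx = n_xyz(i, 0) - n_xyz(j, 0);
            double ddy = n_xyz(i, 1) - n_xyz(j, 1);
            double ddz = n_xyz(i, 2) - n_xyz(j, 2);
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 < c2) {
              if (excl.find(ra * NR + rb) == excl.end()) ++count;
            }
          }
        }
      }
    }
  }
  return count;
}
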