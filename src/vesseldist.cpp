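#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <functional>
using namespace Rcpp;

static const double EDT_INF = 1e20;

// 1-D squared distance transform, lower envelope of parabolas
// (Felzenszwalb & Huttenlocher). f holds source costs, d the result.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -EDT_INF;
  z[1] = EDT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = EDT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (pixel units) to the nearest TRUE pixel.
// All finite outputs are exact integers representable as doubles.
// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(LogicalMatrix target) {
  int nr = target.nrow(), nc = target.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // pass 1: down each column
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = target(i, j) ? 0.0 : EDT_INF;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) out(i, j) = d[i];
  }
  // pass 2: across each row
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = out(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) out(i, j) = d[j];
  }
  return out;
}

// 4-connected components; pixels connect iff both nonzero and carry the same
// region value. Labels are consecutive 1..K in column-major first-encounter
// order (deterministic).
// [[Rcpp::export]]
IntegerMatrix label4_cpp(IntegerMatrix regions) {
  int nr = regions.nrow(), nc = regions.ncol();
  int n = nr * nc;
  std::vector<int> parent(n);
  for (int k = 0; k < n; ++k) parent[k] = k;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int v = regions(i, j);
      if (v == 0) continue;
      int idx = j * nr + i;
      if (i > 0 && regions(i - 1, j) == v) unite(idx, idx - 1);
      if (j > 0 && regions(i, j - 1) == v) unite(idx, idx - nr);
    }
  }
  IntegerMatrix out(nr, nc);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (regions(i, j) == 0) continue;
      int r = find(j * nr + i);
      if (remap[r] == 0) remap[r] = ++next;
      out(i, j) = remap[r];
    }
  }
  return out;
}

// Assign each background pixel within max_dsq (squared px) of a labeled
// pixel to its nearest label; among equidistant labels the smallest id
// wins. Equivalent to a brute-force per-pixel nearest-label search.
// [[Rcpp::export]]
IntegerMatrix assign_nearest_label_cpp(IntegerMatrix labels, NumericMatrix dsq,
                                       double max_dsq) {
  int nr = labels.nrow(), nc = labels.ncol();
  IntegerMatrix out = clone(labels);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (labels(i, j) != 0) continue;
      double d2 = dsq(i, j);
      if (d2 > max_dsq + 1e-9 || d2 >= EDT_INF) continue;
      long long target = (long long)std::llround(d2);
      int w = (int)std::ceil(std::sqrt(d2)) + 1;
      int best = 0;
      for (int dj = -w; dj <= w; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= nc) continue;
        for (int di = -w; di <= w; ++di) {
          int ii = i + di;
          if (ii < 0 || ii >= nr) continue;
          long long dd = (long long)di * di + (long long)dj * dj;
          if (dd != target) continue;
          int lab = labels(ii, jj);
          if (lab > 0 && (best == 0 || lab < best)) best = lab;
        }
      }
      out(i, j) = best;
    }
  }
  return out;
}

// One Jacobi relaxation residual for the discrete diffusion-consumption
// equation: candidate local solve minus current value, zero on Dirichlet
// pixels. Units: mmHg. Zero-flux boundary via cell-centered mirror
// (missing neighbor = center value).
static double residual_at(const NumericMatrix& p, int i, int j, int nr, int nc,
                          double alpha, double km) {
  double c = p(i, j);
  double S = 0.0;
  S += (i > 0) ? p(i - 1, j) : c;
  S += (i < nr - 1) ? p(i + 1, j) : c;
  S += (j > 0) ? p(i, j - 1) : c;
  S += (j < nc - 1) ? p(i, j + 1) : c;
  double cand = S / (4.0 + alpha / (c + km));
  return cand - c;
}

// [[Rcpp::export]]
NumericMatrix oxygen_residual_cpp(NumericMatrix p, LogicalMatrix dirichlet,
                                  double alpha, double km) {
  int nr = p.nrow(), nc = p.ncol();
  NumericMatrix res(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      res(i, j) = dirichlet(i, j) ? 0.0
                                  : residual_at(p, i, j, nr, nc, alpha, km);
  return res;
}

// Red-black SOR for steady-state D lap(p) = M p/(p+km) with Dirichlet
// p = pv on perfused lumen pixels and zero-flux outer boundary.
// alpha = h^2 * M / D (h = pixel size, um). Consumption is lagged in the
// denominator so iterates stay non-negative; p clamped to [0, pv].
// Convergence is declared on the Jacobi residual (mmHg) < tol.
// [[Rcpp::export]]
List solve_oxygen_cpp(LogicalMatrix dirichlet, double pv, double alpha,
                      double km, double tol, int max_iter, double omega,
                      Nullable<NumericMatrix> init = R_NilValue) {
  int nr = dirichlet.nrow(), nc = dirichlet.ncol();
  NumericMatrix p(nr, nc);
  if (init.isNotNull()) {
    NumericMatrix ini(init);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        double v = ini(i, j);
        p(i, j) = (v < 0.0) ? 0.0 : (v > pv ? pv : v);
      }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (dirichlet(i, j)) p(i, j) = pv;

  double maxres = R_PosInf;
  int iter = 0;
  bool converged = false;
  while (iter < max_iter) {
    ++iter;
    for (int color = 0; color < 2; ++color) {
      for (int j = 0; j < nc; ++j) {
        int istart = (color + j) % 2;
        for (int i = istart; i < nr; i += 2) {
          if (dirichlet(i, j)) continue;
          double upd = residual_at(p, i, j, nr, nc, alpha, km);
          double np = p(i, j) + omega * upd;
          if (np < 0.0) np = 0.0;
          if (np > pv) np = pv;
          p(i, j) = np;
        }
      }
    }
    if (iter % 10 == 0 || iter == max_iter) {
      maxres = 0.0;
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i)
          if (!dirichlet(i, j)) {
            double r = std::fabs(residual_at(p, i, j, nr, nc, alpha, km));
            if (r > maxres) maxres = r;
          }
      if (maxres < tol) { converged = true; break; }
    }
    if (iter % 100 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["field"] = p, _["iterations"] = iter,
                      _["max_residual"] = maxres,
                      _["converged"] = converged);
}
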