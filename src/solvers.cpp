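#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Matrix-free Jacobi-preconditioned conjugate gradients on a structured
// stencil with an arbitrary set of link directions. Couplings are
// stored once per link on the lower-index node: coup[k][i] couples node
// i with node i + shift[k]; a zero coupling means no link (Neumann
// face, inactive neighbour, or eliminated Dirichlet neighbour whose
// contribution is already folded into diag/b). The operator is
//   (A x)_i = diag_i x_i - sum_links c_link x_neighbour
// which is symmetric by construction.

static void stencil_apply(const R_xlen_t N, const int nlink,
                          const R_xlen_t* shifts, const double* const* coup,
                          const double* dg, const double* x, double* y) {
  for (R_xlen_t i = 0; i < N; ++i) y[i] = dg[i] * x[i];
  for (int k = 0; k < nlink; ++k) {
    const R_xlen_t s = shifts[k];
    const double* c = coup[k];
    for (R_xlen_t i = 0; i < N - s; ++i) {
      const double ci = c[i];
      if (ci != 0.0) { y[i] -= ci * x[i + s]; y[i + s] -= ci * x[i]; }
    }
  }
}

// [[Rcpp::export(name = ".stencil_pcg")]]
List stencil_pcg(IntegerVector shifts, List coup, NumericVector diag,
                 NumericVector b, NumericVector x0, double tol, int maxit) {
  const R_xlen_t N = diag.size();
  const int nlink = shifts.size();
  if (b.size() != N || x0.size() != N || (int)coup.size() != nlink)
    stop("stencil_pcg: inconsistent array sizes");
  std::vector<R_xlen_t> sh(nlink);
  std::vector<const double*> cp(nlink);
  std::vector<NumericVector> keep(nlink);
  for (int k = 0; k < nlink; ++k) {
    sh[k] = shifts[k];
    if (sh[k] <= 0 || sh[k] >= N) stop("stencil_pcg: invalid shift");
    keep[k] = as<NumericVector>(coup[k]);
    if (keep[k].size() != N) stop("stencil_pcg: coupling size mismatch");
    cp[k] = keep[k].begin();
  }

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> r(N), z(N), p(N), Ap(N), Minv(N);

  double bnorm2 = 0.0;
  for (R_xlen_t i = 0; i < N; ++i) bnorm2 += b[i] * b[i];
  if (bnorm2 == 0.0) {
    NumericVector xout(N, 0.0);
    return List::create(_["x"] = xout, _["iter"] = 0, _["relres"] = 0.0);
  }

  for (R_xlen_t i = 0; i < N; ++i)
    Minv[i] = (diag[i] > 0.0) ? 1.0 / diag[i] : 0.0;

  stencil_apply(N, nlink, sh.data(), cp.data(), diag.begin(), x.data(),
                Ap.data());
  double rnorm2 = 0.0, rz = 0.0;
  for (R_xlen_t i = 0; i < N; ++i) {
    r[i] = (Minv[i] > 0.0) ? b[i] - Ap[i] : 0.0;
    z[i] = Minv[i] * r[i];
    p[i] = z[i];
    rnorm2 += r[i] * r[i];
    rz += r[i] * z[i];
  }

  const double tol2 = tol * tol * bnorm2;
  int iter = 0;
  while (rnorm2 > tol2 && iter < maxit) {
    stencil_apply(N, nlink, sh.data(), cp.data(), diag.begin(), p.data(),
                  Ap.data());
    double pAp = 0.0;
    for (R_xlen_t i = 0; i < N; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0.0) break;  // matrix not SPD on the active set
    const double alpha = rz / pAp;
    rnorm2 = 0.0;
    double rz_new = 0.0;
    for (R_xlen_t i = 0; i < N; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      z[i] = Minv[i] * r[i];
      rnorm2 += r[i] * r[i];
      rz_new += r[i] * z[i];
    }
    const double beta = rz_new / rz;
    rz = rz_new;
    for (R_xlen_t i = 0; i < N; ++i) p[i] = z[i] + beta * p[i];
    ++iter;
  }

  NumericVector xout(x.begin(), x.end());
  return List::create(_["x"] = xout, _["iter"] = iter,
                      _["relres"] = std::sqrt(rnorm2 / bnorm2));
}

// Closest distance from each query point to a triangle mesh
// (point-to-triangle, Ericson's closest-point construction), with a
// centroid-radius cull so large meshes stay fast.

static inline double clamp01(double v) {
  return v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
}

static double point_triangle_dist2(const double* P, const double* A,
                                   const double* B, const double* C) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = B[k] - A[k];
    ac[k] = C[k] - A[k];
    ap[k] = P[k] - A[k];
  }
  const double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  const double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double u = -1, v = -1;
  if (d1 <= 0.0 && d2 <= 0.0) { u = 0; v = 0; }
  double bp[3], cp[3];
  for (int k = 0; k < 3; ++k) { bp[k] = P[k] - B[k]; cp[k] = P[k] - C[k]; }
  const double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  const double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (u < 0 && d3 >= 0.0 && d4 <= d3) { u = 1; v = 0; }
  const double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  const double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (u < 0 && d6 >= 0.0 && d5 <= d6) { u = 0; v = 1; }
  if (u < 0) {
    const double vc = d1 * d4 - d3 * d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) { u = clamp01(d1 / (d1 - d3)); v = 0; }
  }
  if (u < 0) {
    const double vb = d5 * d2 - d1 * d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) { u = 0; v = clamp01(d2 / (d2 - d6)); }
  }
  if (u < 0) {
    const double va = d3 * d6 - d5 * d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
      const double w = clamp01((d4 - d3) / ((d4 - d3) + (d5 - d6)));
      u = 1.0 - w; v = w;
    }
  }
  if (u < 0) {  // interior projection: barycentric coordinates
    const double vc = d1 * d4 - d3 * d2;
    const double vb = d5 * d2 - d1 * d6;
    const double va = d3 * d6 - d5 * d4;
    const double denom = va + vb + vc;
    u = vb / denom;
    v = vc / denom;
  }
  double d2sum = 0.0;
  for (int k = 0; k < 3; ++k) {
    const double q = A[k] + u * ab[k] + v * ac[k] - P[k];
    d2sum += q * q;
  }
  return d2sum;
}

// [[Rcpp::export(name = ".point_mesh_distance")]]
NumericVector point_mesh_distance(NumericMatrix pts, NumericMatrix verts,
                                  IntegerMatrix tris) {
  const int np = pts.nrow(), nt = tris.nrow();
  if (nt == 0) stop("mesh has no triangles");
  std::vector<double> cx(nt), cy(nt), cz(nt), rad(nt);
  std::vector<double> TA(3 * nt), TB(3 * nt), TC(3 * nt);
  for (int t = 0; t < nt; ++t) {
    const int a = tris(t, 0) - 1, b = tris(t, 1) - 1, c = tris(t, 2) - 1;
    for (int k = 0; k < 3; ++k) {
      TA[3 * t + k] = verts(a, k);
      TB[3 * t + k] = verts(b, k);
      TC[3 * t + k] = verts(c, k);
    }
    cx[t] = (TA[3 * t] + TB[3 * t] + TC[3 * t]) / 3.0;
    cy[t] = (TA[3 * t + 1] + TB[3 * t + 1] + TC[3 * t + 1]) / 3.0;
    cz[t] = (TA[3 * t + 2] + TB[3 * t + 2] + TC[3 * t + 2]) / 3.0;
    auto d2c = [&](const double* V) {
      const double dx = V[0] - cx[t], dy = V[1] - cy[t], dz = V[2] - cz[t];
      return dx * dx + dy * dy + dz * dz;
    };
    const double r2 = std::max(d2c(&TA[3 * t]),
                               std::max(d2c(&TB[3 * t]), d2c(&TC[3 * t])));
    rad[t] = std::sqrt(r2);
  }
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    const double P[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double best = R_PosInf;
    for (int t = 0; t < nt; ++t) {
      const double dx = P[0] - cx[t], dy = P[1] - cy[t], dz = P[2] - cz[t];
      const double dc = std::sqrt(dx * dx + dy * dy + dz * dz) - rad[t];
      if (dc * dc >= best && dc > 0.0) continue;
      const double d2 = point_triangle_dist2(P, &TA[3 * t], &TB[3 * t], &TC[3 * t]);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Greedy Poisson-disk thinning of candidate surface points: accept a
// candidate when no already-accepted point lies within radius r. A
// uniform grid hash of cell size r keeps the scan linear.

// [[Rcpp::export(name = ".poisson_disk_thin")]]
IntegerVector poisson_disk_thin(NumericMatrix pts, double r, int nmax) {
  const int n = pts.nrow();
  const double inv = 1.0 / r;
  std::unordered_map<int64_t, std::vector<int>> grid;
  std::vector<int> keep;
  keep.reserve(nmax > 0 ? nmax : n);
  const double r2 = r * r;
  auto key = [&](int ix, int iy, int iz) {
    return (int64_t)ix * 73856093LL ^ (int64_t)iy * 19349663LL ^ (int64_t)iz * 83492791LL;
  };
  for (int i = 0; i < n; ++i) {
    const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    const int ix = (int)std::floor(x * inv), iy = (int)std::floor(y * inv),
              iz = (int)std::floor(z * inv);
    bool ok = true;
    for (int dx = -1; dx <= 1 && ok; ++dx)
      for (int dy = -1; dy <= 1 && ok; ++dy)
        for (int dz = -1; dz <= 1 && ok; ++dz) {
          auto it = grid.find(key(ix + dx, iy + dy, iz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            const double ddx = x - pts(j, 0), ddy = y - pts(j, 1), ddz = z - pts(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz < r2) { ok = false; break; }
          }
        }
    if (ok) {
      keep.push_back(i + 1);
      grid[key(ix, iy, iz)].push_back(i);
      if (nmax > 0 && (int)keep.size() >= nmax) break;
    }
  }
  return IntegerVector(keep.begin(), keep.end());
}
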