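#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// All physical coordinates and direction vectors are in (z, y, x) order,
// matching the R-side array layout dim = c(nz, ny, nx) and the "zyx"
// axis_order of the TIFF sidecar. Voxel (i, j, k) (1-based) has its center
// at ((i-1), (j-1), (k-1)) * spacing + origin.

static inline int idx3(int i, int j, int k, int nz, int ny) {
  // column-major linear index of [i, j, k] (0-based) in dim c(nz, ny, nx)
  return i + nz * (j + (long long)ny * k);
}

// [[Rcpp::export]]
IntegerVector cpp_rasterize_cylinder(int nz, int ny, int nx, double spacing,
                                     NumericVector center, NumericVector axis,
                                     double diameter_um, double length_um,
                                     bool shell, double wall_um) {
  IntegerVector out((R_xlen_t)nz * ny * nx);
  double az = axis[0], ay = axis[1], ax = axis[2];
  double norm = std::sqrt(az * az + ay * ay + ax * ax);
  az /= norm; ay /= norm; ax /= norm;
  double half = length_um / 2.0, r = diameter_um / 2.0;
  double p0z = center[0] - half * az, p0y = center[1] - half * ay,
         p0x = center[2] - half * ax;
  // bounding box in voxel indices, padded by the outer radius
  double loz = std::min(p0z, p0z + length_um * az) - r;
  double hiz = std::max(p0z, p0z + length_um * az) + r;
  double loy = std::min(p0y, p0y + length_um * ay) - r;
  double hiy = std::max(p0y, p0y + length_um * ay) + r;
  double lox = std::min(p0x, p0x + length_um * ax) - r;
  double hix = std::max(p0x, p0x + length_um * ax) + r;
  int i0 = std::max(0, (int)std::floor(loz / spacing));
  int i1 = std::min(nz - 1, (int)std::ceil(hiz / spacing));
  int j0 = std::max(0, (int)std::floor(loy / spacing));
  int j1 = std::min(ny - 1, (int)std::ceil(hiy / spacing));
  int k0 = std::max(0, (int)std::floor(lox / spacing));
  int k1 = std::min(nx - 1, (int)std::ceil(hix / spacing));
  double rin = r - wall_um;
  for (int k = k0; k <= k1; ++k) {
    double qx = k * spacing;
    for (int j = j0; j <= j1; ++j) {
      double qy = j * spacing;
      for (int i = i0; i <= i1; ++i) {
        double qz = i * spacing;
        double wz = qz - p0z, wy = qy - p0y, wx = qx - p0x;
        double t = wz * az + wy * ay + wx * ax;
        if (t < 0) t = 0; else if (t > length_um) t = length_um;
        double dz = wz - t * az, dy = wy - t * ay, dx = wx - t * ax;
        double dist = std::sqrt(dz * dz + dy * dy + dx * dx);
        bool inside = shell ? (dist <= r && dist >= rin) : (dist <= r);
        if (inside) out[idx3(i, j, k, nz, ny)] = 1;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, int nz, int ny, int nx,
                          int connectivity) {
  IntegerVector labels((R_xlen_t)nz * ny * nx);
  // neighbour offsets
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  int nb = (int)di.size();
  int next = 0;
  std::vector<long long> stack;
  for (int k = 0; k < nx; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nz; ++i) {
        long long p = idx3(i, j, k, nz, ny);
        if (!mask[p] || labels[p]) continue;
        ++next;
        labels[p] = next;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          long long q = stack.back(); stack.pop_back();
          int qi = (int)(q % nz);
          int qj = (int)((q / nz) % ny);
          int qk = (int)(q / ((long long)nz * ny));
          for (int m = 0; m < nb; ++m) {
            int ii = qi + di[m], jj = qj + dj[m], kk = qk + dk[m];
            if (ii < 0 || ii >= nz || jj < 0 || jj >= ny || kk < 0 || kk >= nx)
              continue;
            long long s = idx3(ii, jj, kk, nz, ny);
            if (mask[s] && !labels[s]) {
              labels[s] = next;
              stack.push_back(s);
            }
          }
        }
      }
  labels.attr("n_labels") = next;
  return labels;
}

// [[Rcpp::export]]
IntegerVector cpp_resample_nn(IntegerVector vol, int nz, int ny, int nx,
                              double spacing, NumericMatrix basis,
                              NumericVector origin0, NumericVector pitch,
                              int ns, int nr, int nc) {
  // basis columns: u (slice cols), v (slice rows), n (slice normal), zyx;
  // pitch = (along u, along v, along n)
  IntegerVector out((R_xlen_t)ns * nr * nc);
  double uz = basis(0, 0), uy = basis(1, 0), ux = basis(2, 0);
  double vz = basis(0, 1), vy = basis(1, 1), vx = basis(2, 1);
  double wz = basis(0, 2), wy = basis(1, 2), wx = basis(2, 2);
  double pu = pitch[0], pv = pitch[1], pn = pitch[2];
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      for (int s = 0; s < ns; ++s) {
        double pz = origin0[0] + c * pu * uz + r * pv * vz + s * pn * wz;
        double py = origin0[1] + c * pu * uy + r * pv * vy + s * pn * wy;
        double px = origin0[2] + c * pu * ux + r * pv * vx + s * pn * wx;
        int i = (int)std::lround(pz / spacing);
        int j = (int)std::lround(py / spacing);
        int k = (int)std::lround(px / spacing);
        if (i < 0 || i >= nz || j < 0 || j >= ny || k < 0 || k >= nx) continue;
        out[idx3(s, r, c, ns, nr)] = vol[idx3(i, j, k, nz, ny)];
      }
  return out;
}

// [[Rcpp::export]]
List cpp_khachiyan(NumericMatrix P, double tol, int max_iter) {
  // Minimum-volume enclosing ellipsoid in the plane, Khachiyan's
  // barycentric coordinate-descent: lift points to (x, y, 1), iterate
  // u_j <- u_j + step on the point with the largest Mahalanobis value.
  int n = P.nrow();
  std::vector<double> u(n, 1.0 / n);
  double X[9];      // 3x3 scatter sum u_i q_i q_i^T
  double Xi[9];     // inverse
  int it = 0;
  bool converged = false, singular = false;
  for (it = 0; it < max_iter; ++it) {
    for (int m = 0; m < 9; ++m) X[m] = 0.0;
    for (int i = 0; i < n; ++i) {
      double q0 = P(i, 0), q1 = P(i, 1);
      double w = u[i];
      X[0] += w * q0 * q0; X[1] += w * q1 * q0; X[2] += w * q0;
      X[4] += w * q1 * q1; X[5] += w * q1;
    }
    X[3] = X[1]; X[6] = X[2]; X[7] = X[5]; X[8] = 1.0; // sum u_i = 1
    double det = X[0] * (X[4] * X[8] - X[5] * X[7])
               - X[1] * (X[3] * X[8] - X[5] * X[6])
               + X[2] * (X[3] * X[7] - X[4] * X[6]);
    if (std::fabs(det) < 1e-300) { singular = true; break; }
    Xi[0] = (X[4] * X[8] - X[5] * X[7]) / det;
    Xi[1] = (X[2] * X[7] - X[1] * X[8]) / det;
    Xi[2] = (X[1] * X[5] - X[2] * X[4]) / det;
    Xi[3] = (X[5] * X[6] - X[3] * X[8]) / det;
    Xi[4] = (X[0] * X[8] - X[2] * X[6]) / det;
    Xi[5] = (X[2] * X[3] - X[0] * X[5]) / det;
    Xi[6] = (X[3] * X[7] - X[4] * X[6]) / det;
    Xi[7] = (X[1] * X[6] - X[0] * X[7]) / det;
    Xi[8] = (X[0] * X[4] - X[1] * X[3]) / det;
    double maxM = -1.0, minM = R_PosInf;
    int jmax = 0, jmin = -1;
    for (int i = 0; i < n; ++i) {
      double q0 = P(i, 0), q1 = P(i, 1);
      double m0 = Xi[0] * q0 + Xi[1] * q1 + Xi[2];
      double m1 = Xi[3] * q0 + Xi[4] * q1 + Xi[5];
      double m2 = Xi[6] * q0 + Xi[7] * q1 + Xi[8];
      double M = q0 * m0 + q1 * m1 + m2;
      if (M > maxM) { maxM = M; jmax = i; }
      if (u[i] > 1e-12 && M < minM) { minM = M; jmin = i; }
    }
    if (maxM <= 3.0 * (1.0 + tol)) { converged = true; break; }
    // Wolfe away-steps (Todd-Yildirim): when the worst violation is an
    // over-weighted support point, shrink its weight instead; this makes
    // the first-order iteration linearly convergent.
    int j = jmax;
    if (jmin >= 0 && (3.0 - minM) > (maxM - 3.0)) j = jmin;
    double Mj = (j == jmax) ? maxM : minM;
    double step = (Mj - 3.0) / (3.0 * (Mj - 1.0));
    double floor_step = -u[j] / (1.0 - u[j]);
    if (step < floor_step) step = floor_step;
    for (int i = 0; i < n; ++i) u[i] *= (1.0 - step);
    u[j] += step;
  }
  double cz0 = 0.0, cz1 = 0.0;
  for (int i = 0; i < n; ++i) { cz0 += u[i] * P(i, 0); cz1 += u[i] * P(i, 1); }
  double s00 = 0.0, s01 = 0.0, s11 = 0.0;
  for (int i = 0; i < n; ++i) {
    double d0 = P(i, 0) - cz0, d1 = P(i, 1) - cz1;
    s00 += u[i] * d0 * d0; s01 += u[i] * d0 * d1; s11 += u[i] * d1 * d1;
  }
  // A = inv(S) / 2 so that (x - c)^T A (x - c) <= 1
  double detS = s00 * s11 - s01 * s01;
  NumericMatrix A(2, 2);
  bool degenerate = singular || detS < 1e-300;
  if (!degenerate) {
    A(0, 0) = s11 / detS / 2.0;
    A(0, 1) = A(1, 0) = -s01 / detS / 2.0;
    A(1, 1) = s00 / detS / 2.0;
  }
  return List::create(_["center"] = NumericVector::create(cz0, cz1),
                      _["A"] = A, _["iterations"] = it + 1,
                      _["converged"] = converged,
                      _["degenerate"] = degenerate);
}
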