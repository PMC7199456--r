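// Support ops: zero-padded window extraction, trilinear resampling,
// nearest-neighbour surface distances, cavity filling and region growing.
#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int X, int Y) {
  return (z * Y + y) * X + x;
}

// Extract a cubic side-d window whose low corner is `center - floor(d/2)`
// (0-based voxel coordinates); voxels outside the volume are 0.
// vol: array dim (X, Y, Z, C); returns (d, d, d, C).
// [[Rcpp::export]]
NumericVector cpp_extract_window(NumericVector vol, IntegerVector center, int d) {
  IntegerVector dm = vol.attr("dim");
  const int X = dm[0], Y = dm[1], Z = dm[2], C = (dm.size() > 3) ? dm[3] : 1;
  const int half = d / 2;
  const int x0 = center[0] - half, y0 = center[1] - half, z0 = center[2] - half;
  NumericVector out(d * d * d * C);
  const int V = d * d * d, Vin = X * Y * Z;
  for (int c = 0; c < C; ++c) {
    const double* vp = &vol[0] + (size_t)c * Vin;
    double* op = &out[0] + (size_t)c * V;
    for (int z = 0; z < d; ++z) {
      int zz = z0 + z;
      for (int y = 0; y < d; ++y) {
        int yy = y0 + y;
        bool in_yz = (zz >= 0 && zz < Z && yy >= 0 && yy < Y);
        for (int x = 0; x < d; ++x) {
          int xx = x0 + x;
          op[idx3(x, y, z, d, d)] =
            (in_yz && xx >= 0 && xx < X) ? vp[idx3(xx, yy, zz, X, Y)] : 0.0;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(d, d, d, C);
  return out;
}

// Trilinear resize of a cubic (D, D, D, C) array to side dout, using the
// half-voxel-centre convention: src = (i + 0.5) * D/dout - 0.5, clamped.
// [[Rcpp::export]]
NumericVector cpp_resize3(NumericVector arr, int dout) {
  IntegerVector dm = arr.attr("dim");
  const int D = dm[0], C = (dm.size() > 3) ? dm[3] : 1;
  if (dm[1] != D || dm[2] != D) stop("cubic input required");
  const double f = (double)D / dout;
  std::vector<int> lo(dout); std::vector<double> w(dout);
  for (int i = 0; i < dout; ++i) {
    double s = (i + 0.5) * f - 0.5;
    if (s < 0) s = 0; if (s > D - 1) s = D - 1;
    int l = (int)std::floor(s);
    if (l > D - 2) l = D - 2;
    lo[i] = l; w[i] = s - l;
  }
  NumericVector out(dout * dout * dout * C);
  const int Vin = D * D * D, V = dout * dout * dout;
  for (int c = 0; c < C; ++c) {
    const double* vp = &arr[0] + (size_t)c * Vin;
    double* op = &out[0] + (size_t)c * V;
    for (int z = 0; z < dout; ++z) {
      int z0 = lo[z]; double wz = w[z];
      for (int y = 0; y < dout; ++y) {
        int y0 = lo[y]; double wy = w[y];
        for (int x = 0; x < dout; ++x) {
          int x0 = lo[x]; double wx = w[x];
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                double wt = (dx ? wx : 1 - wx) * (dy ? wy : 1 - wy) * (dz ? wz : 1 - wz);
                acc += wt * vp[idx3(x0 + dx, y0 + dy, z0 + dz, D, D)];
              }
          op[idx3(x, y, z, dout, dout)] = acc;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(dout, dout, dout, C);
  return out;
}

// For each row of A (points, in voxel indices), the Euclidean distance in mm
// to the nearest row of B, under anisotropic voxel spacing.
// [[Rcpp::export]]
NumericVector cpp_nn_dists(NumericMatrix A, NumericMatrix B, NumericVector spacing) {
  const int n = A.nrow(), m = B.nrow();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double ax = A(i, 0) * sx, ay = A(i, 1) * sy, az = A(i, 2) * sz;
    for (int j = 0; j < m; ++j) {
      double dx = ax - B(j, 0) * sx, dy = ay - B(j, 1) * sy, dz = az - B(j, 2) * sz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Fill interior cavities: background components (6-connectivity) not
// reachable from the volume border become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask) {
  IntegerVector dm = mask.attr("dim");
  const int X = dm[0], Y = dm[1], Z = dm[2], V = X * Y * Z;
  std::vector<char> outside(V, 0);
  std::queue<int> q;
  auto push_bg = [&](int x, int y, int z) {
    int i = idx3(x, y, z, X, Y);
    if (!mask[i] && !outside[i]) { outside[i] = 1; q.push(i); }
  };
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x)
        if (x == 0 || y == 0 || z == 0 || x == X - 1 || y == Y - 1 || z == Z - 1)
          push_bg(x, y, z);
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    int i = q.front(); q.pop();
    int z = i / (X * Y), r = i % (X * Y), y = r / X, x = r % X;
    for (int k = 0; k < 6; ++k) {
      int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= X || yy >= Y || zz >= Z) continue;
      push_bg(xx, yy, zz);
    }
  }
  LogicalVector out(V);
  for (int i = 0; i < V; ++i) out[i] = mask[i] || !outside[i];
  out.attr("dim") = dm;
  return out;
}

// Seeded region growing on one intensity channel: FIFO flood fill over the
// 6-neighbourhood, admitting a neighbour when |value - running region mean|
// is strictly below `threshold`.  Deterministic for a fixed seed point.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector img, IntegerVector seed, double threshold) {
  IntegerVector dm = img.attr("dim");
  const int X = dm[0], Y = dm[1], Z = dm[2], V = X * Y * Z;
  LogicalVector out(V);
  out.attr("dim") = IntegerVector::create(X, Y, Z);
  int si = idx3(seed[0], seed[1], seed[2], X, Y);
  std::queue<int> q;
  out[si] = true; q.push(si);
  double sum = img[si]; long cnt = 1;
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    int i = q.front(); q.pop();
    int z = i / (X * Y), r = i % (X * Y), y = r / X, x = r % X;
    for (int k = 0; k < 6; ++k) {
      int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= X || yy >= Y || zz >= Z) continue;
      int j = idx3(xx, yy, zz, X, Y);
      if (out[j]) continue;
      if (std::abs(img[j] - sum / cnt) < threshold) {
        out[j] = true; q.push(j);
        sum += img[j]; ++cnt;
      }
    }
  }
  return out;
}
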