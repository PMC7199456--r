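// 3D U-Net core: batched im2col 3x3x3 convolutions, instance
// normalization, 2x max pooling, nearest-neighbour upsampling, and a
// hand-derived backward pass.  The whole stack is templated on the scalar
// type: the double instantiation backs the tight finite-difference
// gradient checks, the float instantiation is the training default (same
// algorithm, faster GEMMs).  Everything is single-threaded and free of
// hidden state, so training is bit-reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double IN_EPS = 1e-5;
// leaky-ReLU slope: keeps gradient alive in every unit, so narrow
// networks cannot lose filters to dead initializations
static const double LEAKY = 0.01;

// Batch tensors are (N*V) x C matrices: V = s^3 voxels per sample
// (x fastest), sample n occupying the row block [n*V, (n+1)*V).  This is
// the memory layout of an R array with dim c(s, s, s, C) stacked over n.

template <typename T> struct ConvP { arma::Mat<T> W; arma::Col<T> b; };
template <typename T> struct NormP { arma::Col<T> g; arma::Col<T> b; };
template <typename T> struct Block {
  ConvP<T> c1; NormP<T> n1; ConvP<T> c2; NormP<T> n2;
};

template <typename T> struct UNetP {
  int d, in_ch, base, depth;
  bool use_norm;
  std::vector<Block<T> > enc, dec;
  Block<T> bott;
  arma::Mat<T> fW;
  T fb;
};

static int enc_in(int in_ch, int base, int st) {
  return st == 0 ? in_ch : base << (st - 1);
}
static int enc_out(int base, int st) { return base << st; }
static int dec_in(int base, int depth, int st) {
  int from_below = (st == depth - 1) ? (base << depth) : (base << (st + 1));
  return (base << st) + from_below;
}
static int dec_out(int base, int st) { return base << st; }

template <typename T>
arma::Mat<T> get_mat(const List& lp, const std::string& nm, int r, int c) {
  NumericVector v = lp[nm];
  if ((int)v.size() != r * c) stop("parameter '%s' has wrong size", nm.c_str());
  arma::Mat<T> out(r, c);
  for (int i = 0; i < r * c; ++i) out[i] = (T)v[i];
  return out;
}
template <typename T>
arma::Col<T> get_vec(const List& lp, const std::string& nm, int n) {
  NumericVector v = lp[nm];
  if ((int)v.size() != n) stop("parameter '%s' has wrong size", nm.c_str());
  arma::Col<T> out(n);
  for (int i = 0; i < n; ++i) out[i] = (T)v[i];
  return out;
}

template <typename T>
Block<T> get_block(const List& lp, const std::string& pre, int cin, int cout,
                   bool use_norm) {
  Block<T> b;
  b.c1.W = get_mat<T>(lp, pre + "c1_W", 27 * cin, cout);
  b.c1.b = get_vec<T>(lp, pre + "c1_b", cout);
  b.c2.W = get_mat<T>(lp, pre + "c2_W", 27 * cout, cout);
  b.c2.b = get_vec<T>(lp, pre + "c2_b", cout);
  if (use_norm) {
    b.n1.g = get_vec<T>(lp, pre + "n1_g", cout);
    b.n1.b = get_vec<T>(lp, pre + "n1_b", cout);
    b.n2.g = get_vec<T>(lp, pre + "n2_g", cout);
    b.n2.b = get_vec<T>(lp, pre + "n2_b", cout);
  }
  return b;
}

template <typename T>
UNetP<T> parse_params(const List& lp, int d, int in_ch, int base, int depth,
                      bool use_norm) {
  UNetP<T> p; p.d = d; p.in_ch = in_ch; p.base = base; p.depth = depth;
  p.use_norm = use_norm;
  for (int st = 0; st < depth; ++st)
    p.enc.push_back(get_block<T>(lp, "e" + std::to_string(st + 1),
                                 enc_in(in_ch, base, st), enc_out(base, st),
                                 use_norm));
  p.bott = get_block<T>(lp, "b", base << (depth - 1), base << depth, use_norm);
  for (int st = 0; st < depth; ++st)
    p.dec.push_back(get_block<T>(lp, "d" + std::to_string(st + 1),
                                 dec_in(base, depth, st), dec_out(base, st),
                                 use_norm));
  p.fW = get_mat<T>(lp, "f_W", base, 1);
  p.fb = (T)as<double>(lp["f_b"]);
  return p;
}

// ---- im2col (column r = tap k of channel c, contiguous over voxels) ----

template <typename T>
arma::Mat<T> im2col(const arma::Mat<T>& X, int s, int N) {
  const int V = s * s * s, C = X.n_cols;
  arma::Mat<T> col((arma::uword)N * V, (arma::uword)27 * C);
  for (int c = 0; c < C; ++c) {
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int k = (kx + 1) + 3 * (ky + 1) + 9 * (kz + 1);
          T* dst0 = col.colptr(27 * c + k);
          const int xlo = std::max(0, -kx), xhi = std::min(s, s - kx);
          for (int n = 0; n < N; ++n) {
            const T* src = X.colptr(c) + (size_t)n * V;
            T* dst = dst0 + (size_t)n * V;
            for (int z = 0; z < s; ++z) {
              const int zz = z + kz;
              if (zz < 0 || zz >= s) {
                std::fill(dst + (size_t)z * s * s, dst + (size_t)(z + 1) * s * s, (T)0);
                continue;
              }
              for (int y = 0; y < s; ++y) {
                const int yy = y + ky;
                T* drow = dst + ((size_t)z * s + y) * s;
                if (yy < 0 || yy >= s) { std::fill(drow, drow + s, (T)0); continue; }
                const T* srow = src + ((size_t)zz * s + yy) * s;
                if (xlo > 0) std::fill(drow, drow + xlo, (T)0);
                std::copy(srow + xlo + kx, srow + xhi + kx, drow + xlo);
                if (xhi < s) std::fill(drow + xhi, drow + s, (T)0);
              }
            }
          }
        }
  }
  return col;
}

template <typename T>
arma::Mat<T> col2im(const arma::Mat<T>& dcol, int s, int N, int C) {
  const int V = s * s * s;
  arma::Mat<T> dX((arma::uword)N * V, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int k = (kx + 1) + 3 * (ky + 1) + 9 * (kz + 1);
          const T* src0 = dcol.colptr(27 * c + k);
          const int xlo = std::max(0, -kx), xhi = std::min(s, s - kx);
          for (int n = 0; n < N; ++n) {
            T* dst = dX.colptr(c) + (size_t)n * V;
            const T* src = src0 + (size_t)n * V;
            for (int z = 0; z < s; ++z) {
              const int zz = z + kz;
              if (zz < 0 || zz >= s) continue;
              for (int y = 0; y < s; ++y) {
                const int yy = y + ky;
                if (yy < 0 || yy >= s) continue;
                T* drow = dst + ((size_t)zz * s + yy) * s + kx;
                const T* srow = src + ((size_t)z * s + y) * s;
                for (int x = xlo; x < xhi; ++x) drow[x] += srow[x];
              }
            }
          }
        }
  }
  return dX;
}

// ---- layers -----------------------------------------------------------

template <typename T> struct NormCache { arma::Mat<T> xhat; arma::Mat<T> invstd; };

template <typename T>
arma::Mat<T> inorm_relu_fwd(const arma::Mat<T>& z, const NormP<T>& p, int V, int N,
                            NormCache<T>& cc) {
  const int C = z.n_cols;
  cc.xhat.set_size(z.n_rows, C);
  cc.invstd.set_size(N, C);
  arma::Mat<T> y(z.n_rows, C);
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const T* zc = z.colptr(c) + (size_t)n * V;
      T* xh = cc.xhat.colptr(c) + (size_t)n * V;
      T* yc = y.colptr(c) + (size_t)n * V;
      double m = 0;
      for (int i = 0; i < V; ++i) m += zc[i];
      m /= V;
      double var = 0;
      for (int i = 0; i < V; ++i) { double d = zc[i] - m; var += d * d; }
      var /= V;
      const T is = (T)(1.0 / std::sqrt(var + IN_EPS));
      cc.invstd(n, c) = is;
      const T g = p.g[c], b = p.b[c], mm = (T)m;
      for (int i = 0; i < V; ++i) {
        xh[i] = (zc[i] - mm) * is;
        T v = g * xh[i] + b;
        yc[i] = v > 0 ? v : (T)LEAKY * v;   // fused leaky ReLU
      }
    }
  }
  return y;
}

// backward through ReLU (mask from y) + instance norm
template <typename T>
arma::Mat<T> inorm_relu_bwd(const arma::Mat<T>& dy, const arma::Mat<T>& y,
                            const NormP<T>& p, int V, int N,
                            const NormCache<T>& cc,
                            arma::Col<T>& dg, arma::Col<T>& db) {
  const int C = dy.n_cols;
  arma::Mat<T> dz(dy.n_rows, C);
  for (int c = 0; c < C; ++c) {
    double dgc = 0, dbc = 0;
    for (int n = 0; n < N; ++n) {
      const T* dyc = dy.colptr(c) + (size_t)n * V;
      const T* yc = y.colptr(c) + (size_t)n * V;
      const T* xh = cc.xhat.colptr(c) + (size_t)n * V;
      T* dzc = dz.colptr(c) + (size_t)n * V;
      double m1 = 0, m2 = 0;
      for (int i = 0; i < V; ++i) {
        T d = yc[i] > 0 ? dyc[i] : (T)LEAKY * dyc[i];
        dgc += (double)d * xh[i];
        dbc += d;
        T dxh = d * p.g[c];
        dzc[i] = dxh;                     // temporarily store dxhat
        m1 += dxh; m2 += (double)dxh * xh[i];
      }
      m1 /= V; m2 /= V;
      const T is = cc.invstd(n, c), tm1 = (T)m1, tm2 = (T)m2;
      for (int i = 0; i < V; ++i)
        dzc[i] = is * (dzc[i] - tm1 - xh[i] * tm2);
    }
    dg[c] += (T)dgc; db[c] += (T)dbc;
  }
  return dz;
}

template <typename T>
arma::Mat<T> maxpool_fwd(const arma::Mat<T>& x, int s, int N, arma::umat& idx) {
  const int h = s / 2, V = s * s * s, H = h * h * h, C = x.n_cols;
  arma::Mat<T> out((arma::uword)N * H, C);
  idx.set_size((arma::uword)N * H, C);
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const T* xc = x.colptr(c) + (size_t)n * V;
      T* oc = out.colptr(c) + (size_t)n * H;
      arma::uword* ic = idx.colptr(c) + (size_t)n * H;
      for (int z = 0; z < h; ++z)
        for (int y = 0; y < h; ++y)
          for (int xq = 0; xq < h; ++xq) {
            T best = -std::numeric_limits<T>::infinity();
            int bi = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  int i = ((2 * z + dz) * s + (2 * y + dy)) * s + (2 * xq + dx);
                  if (xc[i] > best) { best = xc[i]; bi = i; }
                }
            oc[(z * h + y) * h + xq] = best;
            ic[(z * h + y) * h + xq] = (size_t)n * V + bi;
          }
    }
  }
  return out;
}

template <typename T>
arma::Mat<T> maxpool_bwd(const arma::Mat<T>& dout, const arma::umat& idx,
                         int s, int N, int C) {
  arma::Mat<T> dx((arma::uword)N * s * s * s, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    T* dxc = dx.colptr(c);
    const T* dc = dout.colptr(c);
    const arma::uword* ic = idx.colptr(c);
    for (arma::uword o = 0; o < dout.n_rows; ++o) dxc[ic[o]] += dc[o];
  }
  return dx;
}

template <typename T>
arma::Mat<T> upsample_fwd(const arma::Mat<T>& x, int h, int N) {
  const int s = 2 * h, V = s * s * s, H = h * h * h, C = x.n_cols;
  arma::Mat<T> out((arma::uword)N * V, C);
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const T* xc = x.colptr(c) + (size_t)n * H;
      T* oc = out.colptr(c) + (size_t)n * V;
      for (int z = 0; z < s; ++z)
        for (int y = 0; y < s; ++y) {
          const T* row = xc + ((size_t)(z / 2) * h + y / 2) * h;
          T* orow = oc + ((size_t)z * s + y) * s;
          for (int xq = 0; xq < s; ++xq) orow[xq] = row[xq / 2];
        }
    }
  return out;
}

template <typename T>
arma::Mat<T> upsample_bwd(const arma::Mat<T>& dout, int h, int N) {
  const int s = 2 * h, V = s * s * s, H = h * h * h, C = dout.n_cols;
  arma::Mat<T> dx((arma::uword)N * H, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const T* oc = dout.colptr(c) + (size_t)n * V;
      T* xc = dx.colptr(c) + (size_t)n * H;
      for (int z = 0; z < s; ++z)
        for (int y = 0; y < s; ++y) {
          T* row = xc + ((size_t)(z / 2) * h + y / 2) * h;
          const T* orow = oc + ((size_t)z * s + y) * s;
          for (int xq = 0; xq < s; ++xq) row[xq / 2] += orow[xq];
        }
    }
  return dx;
}

// ---- block forward/backward ------------------------------------------

template <typename T> struct BlockCache {
  arma::Mat<T> in, mid, y2;
  NormCache<T> nc1, nc2;
};

template <typename T>
arma::Mat<T> relu_inplace(arma::Mat<T>& a) {
  T* p = a.memptr();
  for (arma::uword i = 0; i < a.n_elem; ++i)
    if (p[i] < 0) p[i] *= (T)LEAKY;
  return a;
}

template <typename T>
arma::Mat<T> block_fwd(const arma::Mat<T>& x, const Block<T>& b, int s, int N,
                       bool use_norm, BlockCache<T>& cc, bool keep) {
  const int V = s * s * s;
  if (keep) cc.in = x;
  arma::Mat<T> z = im2col(x, s, N) * b.c1.W;
  z.each_row() += b.c1.b.t();
  cc.mid = use_norm ? inorm_relu_fwd(z, b.n1, V, N, cc.nc1) : relu_inplace(z);
  z = im2col(cc.mid, s, N) * b.c2.W;
  z.each_row() += b.c2.b.t();
  cc.y2 = use_norm ? inorm_relu_fwd(z, b.n2, V, N, cc.nc2) : relu_inplace(z);
  if (!keep) { cc.in.reset(); cc.nc1.xhat.reset(); cc.nc2.xhat.reset(); }
  return cc.y2;
}

template <typename T> struct BlockGrad {
  arma::Mat<T> dW1, dW2; arma::Col<T> db1, dg1, dn1b, db2, dg2, dn2b;
  void init(const Block<T>& b) {
    dW1.zeros(b.c1.W.n_rows, b.c1.W.n_cols); db1.zeros(b.c1.b.n_elem);
    dg1.zeros(b.n1.g.n_elem); dn1b.zeros(b.n1.g.n_elem);
    dW2.zeros(b.c2.W.n_rows, b.c2.W.n_cols); db2.zeros(b.c2.b.n_elem);
    dg2.zeros(b.n2.g.n_elem); dn2b.zeros(b.n2.g.n_elem);
  }
};

// backward through the leaky ReLU (mask from the post-activation y;
// y < 0 iff the pre-activation was negative)
template <typename T>
arma::Mat<T> relu_bwd(const arma::Mat<T>& dy, const arma::Mat<T>& y) {
  arma::Mat<T> dz = dy;
  T* p = dz.memptr();
  const T* yp = y.memptr();
  for (arma::uword i = 0; i < dz.n_elem; ++i)
    if (yp[i] <= 0) p[i] *= (T)LEAKY;
  return dz;
}

template <typename T>
arma::Mat<T> block_bwd(const arma::Mat<T>& dy, const Block<T>& b, int s, int N,
                       bool use_norm, const BlockCache<T>& cc, BlockGrad<T>& g) {
  const int V = s * s * s;
  arma::Mat<T> dz = use_norm
    ? inorm_relu_bwd(dy, cc.y2, b.n2, V, N, cc.nc2, g.dg2, g.dn2b)
    : relu_bwd(dy, cc.y2);
  {
    arma::Mat<T> col = im2col(cc.mid, s, N);
    g.dW2 += col.t() * dz;
  }
  g.db2 += arma::sum(dz, 0).t();
  arma::Mat<T> dmid = col2im<T>(dz * b.c2.W.t(), s, N, cc.mid.n_cols);
  dz = use_norm
    ? inorm_relu_bwd(dmid, cc.mid, b.n1, V, N, cc.nc1, g.dg1, g.dn1b)
    : relu_bwd(dmid, cc.mid);
  {
    arma::Mat<T> col = im2col(cc.in, s, N);
    g.dW1 += col.t() * dz;
  }
  g.db1 += arma::sum(dz, 0).t();
  return col2im<T>(dz * b.c1.W.t(), s, N, cc.in.n_cols);
}

// ---- whole network ----------------------------------------------------

template <typename T> struct NetCache {
  UNetP<T> p;
  int N;
  std::vector<BlockCache<T> > enc, dec;
  std::vector<arma::umat> pool_idx;
  BlockCache<T> bott;
  arma::Mat<T> last;
};

template <typename T>
arma::Col<T> net_fwd(const UNetP<T>& p, const arma::Mat<T>& x0, int N,
                     NetCache<T>& cc, bool keep) {
  cc.p = p; cc.N = N;
  cc.enc.resize(p.depth); cc.dec.resize(p.depth); cc.pool_idx.resize(p.depth);
  arma::Mat<T> cur = x0;
  int s = p.d;
  std::vector<arma::Mat<T> > skips(p.depth);
  for (int st = 0; st < p.depth; ++st) {
    cur = block_fwd(cur, p.enc[st], s, N, p.use_norm, cc.enc[st], keep);
    skips[st] = cur;
    cur = maxpool_fwd(cur, s, N, cc.pool_idx[st]);
    s /= 2;
  }
  cur = block_fwd(cur, p.bott, s, N, p.use_norm, cc.bott, keep);
  for (int st = p.depth - 1; st >= 0; --st) {
    arma::Mat<T> up = upsample_fwd(cur, s, N);
    s *= 2;
    arma::Mat<T> cat = arma::join_horiz(skips[st], up);
    cur = block_fwd(cat, p.dec[st], s, N, p.use_norm, cc.dec[st], keep);
  }
  if (keep) cc.last = cur;
  return cur * p.fW + p.fb;
}

template <typename T>
List net_bwd(const NetCache<T>& cc, const arma::Col<T>& dl, const List& params) {
  const UNetP<T>& p = cc.p;
  const int N = cc.N;
  std::vector<BlockGrad<T> > genc(p.depth), gdec(p.depth);
  BlockGrad<T> gbott; gbott.init(p.bott);
  for (int st = 0; st < p.depth; ++st) {
    genc[st].init(p.enc[st]); gdec[st].init(p.dec[st]);
  }
  arma::Mat<T> dfW = cc.last.t() * dl;
  T dfb = arma::accu(dl);
  arma::Mat<T> dcur = dl * p.fW.t();
  std::vector<arma::Mat<T> > dskips(p.depth);
  int s = p.d;
  for (int st = 0; st < p.depth; ++st) {   // decoder, fine to coarse
    arma::Mat<T> dcat = block_bwd(dcur, p.dec[st], s, N, p.use_norm, cc.dec[st], gdec[st]);
    const int sc = p.base << st;           // skip channel count at stage st
    dskips[st] = dcat.cols(0, sc - 1);
    s /= 2;
    dcur = upsample_bwd(arma::Mat<T>(dcat.cols(sc, dcat.n_cols - 1)), s, N);
  }
  dcur = block_bwd(dcur, p.bott, s, N, p.use_norm, cc.bott, gbott);
  for (int st = p.depth - 1; st >= 0; --st) {
    arma::Mat<T> dpool = maxpool_bwd(dcur, cc.pool_idx[st], 2 * s, N, dcur.n_cols);
    s *= 2;
    dpool += dskips[st];
    dcur = block_bwd(dpool, p.enc[st], s, N, p.use_norm, cc.enc[st], genc[st]);
  }

  List out;
  auto put_vec = [&](const std::string& nm, const arma::Col<T>& v) {
    NumericVector r(v.n_elem);
    for (arma::uword i = 0; i < v.n_elem; ++i) r[i] = v[i];
    out[nm] = r;
  };
  auto put_mat = [&](const std::string& nm, const arma::Mat<T>& m) {
    NumericVector r(m.n_elem);
    for (arma::uword i = 0; i < m.n_elem; ++i) r[i] = m[i];
    NumericVector tmpl = params[nm];
    if (!Rf_isNull(tmpl.attr("dim"))) r.attr("dim") = tmpl.attr("dim");
    out[nm] = r;
  };
  auto put_block = [&](const std::string& pre, const BlockGrad<T>& g) {
    put_mat(pre + "c1_W", g.dW1); put_vec(pre + "c1_b", g.db1);
    if (p.use_norm) { put_vec(pre + "n1_g", g.dg1); put_vec(pre + "n1_b", g.dn1b); }
    put_mat(pre + "c2_W", g.dW2); put_vec(pre + "c2_b", g.db2);
    if (p.use_norm) { put_vec(pre + "n2_g", g.dg2); put_vec(pre + "n2_b", g.dn2b); }
  };
  for (int st = 0; st < p.depth; ++st)
    put_block("e" + std::to_string(st + 1), genc[st]);
  put_block("b", gbott);
  for (int st = 0; st < p.depth; ++st)
    put_block("d" + std::to_string(st + 1), gdec[st]);
  put_mat("f_W", dfW);
  out["f_b"] = (double)dfb;
  return out;
}

// ---- exported interface ----------------------------------------------

template <typename T>
arma::Mat<T> batch_from_r(const NumericVector& x, int V, int C, int N) {
  // R layout (V, C, N) -> rows (N*V) x C with sample-blocked rows
  arma::Mat<T> X((arma::uword)N * V, C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = &x[0] + ((size_t)n * C + c) * V;
      T* dst = X.colptr(c) + (size_t)n * V;
      for (int i = 0; i < V; ++i) dst[i] = (T)src[i];
    }
  return X;
}

template <typename T>
NumericVector run_forward(List params, NumericVector x, int d, int in_ch,
                          int base, int depth, bool use_norm) {
  UNetP<T> p = parse_params<T>(params, d, in_ch, base, depth, use_norm);
  const int V = d * d * d;
  const int N = x.size() / (V * in_ch);
  if ((int)x.size() != V * in_ch * N) stop("input size mismatch");
  arma::Mat<T> X = batch_from_r<T>(x, V, in_ch, N);
  NetCache<T> cc;
  arma::Col<T> l = net_fwd<T>(p, X, N, cc, false);
  NumericVector out(l.n_elem);
  for (arma::uword i = 0; i < l.n_elem; ++i) out[i] = l[i];
  out.attr("dim") = IntegerVector::create(d, d, d, N);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_unet_forward(List params, NumericVector x, int d, int in_ch,
                               int base, int depth, bool use_norm = false,
                               bool single = true) {
  return single ? run_forward<float>(params, x, d, in_ch, base, depth, use_norm)
                : run_forward<double>(params, x, d, in_ch, base, depth, use_norm);
}

struct CacheHolder {
  bool single;
  NetCache<float> cf;
  NetCache<double> cd;
  List params;
};

// forward pass that keeps the layer caches alive for one backward call
// [[Rcpp::export]]
List cpp_unet_fwd_cached(List params, NumericVector x, int d, int in_ch,
                         int base, int depth, bool use_norm = false,
                         bool single = true) {
  const int V = d * d * d;
  const int N = x.size() / (V * in_ch);
  if ((int)x.size() != V * in_ch * N) stop("input size mismatch");
  XPtr<CacheHolder> ptr(new CacheHolder(), true);
  ptr->single = single;
  ptr->params = params;
  NumericVector out((size_t)V * N);
  if (single) {
    UNetP<float> p = parse_params<float>(params, d, in_ch, base, depth, use_norm);
    arma::Mat<float> X = batch_from_r<float>(x, V, in_ch, N);
    arma::Col<float> l = net_fwd<float>(p, X, N, ptr->cf, true);
    for (arma::uword i = 0; i < l.n_elem; ++i) out[i] = l[i];
  } else {
    UNetP<double> p = parse_params<double>(params, d, in_ch, base, depth, use_norm);
    arma::Mat<double> X = batch_from_r<double>(x, V, in_ch, N);
    arma::Col<double> l = net_fwd<double>(p, X, N, ptr->cd, true);
    for (arma::uword i = 0; i < l.n_elem; ++i) out[i] = l[i];
  }
  out.attr("dim") = IntegerVector::create(d, d, d, N);
  return List::create(_["logits"] = out, _["cache"] = ptr);
}

// [[Rcpp::export]]
List cpp_unet_bwd_cached(SEXP cache, NumericVector dlogits) {
  XPtr<CacheHolder> ptr(cache);
  List out;
  if (ptr->single) {
    arma::Col<float> dl(dlogits.size());
    for (int i = 0; i < (int)dlogits.size(); ++i) dl[i] = (float)dlogits[i];
    out = net_bwd<float>(ptr->cf, dl, ptr->params);
  } else {
    arma::Col<double> dl(dlogits.size());
    for (int i = 0; i < (int)dlogits.size(); ++i) dl[i] = dlogits[i];
    out = net_bwd<double>(ptr->cd, dl, ptr->params);
  }
  // release the layer caches now: the C++ heap is invisible to R's
  // garbage collector, so waiting for finalizers would accumulate
  // gigabytes over a training run
  ptr->cf = NetCache<float>();
  ptr->cd = NetCache<double>();
  return out;
}
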