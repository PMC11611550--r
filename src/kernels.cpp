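// Compiled numerical kernels: 3D convolution (im2col + GEMM) with analytic
// gradients, separable Gaussian and box filters, trilinear resampling and
// 3D connected-component labelling. Feature maps are R arrays with dim
// (X, Y, Z, C) in column-major order; kernels are (kx, ky, kz, Cin, Cout).
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Transposed im2col: Nout x (kx*ky*kz*Cin), zero padding. Each column is
// one kernel offset; for stride 1 the inner loop is a contiguous copy.
static arma::mat im2col_t(const double* x, int X, int Y, int Z, int C,
                          int kx, int ky, int kz, int stride, int pad,
                          int OX, int OY, int OZ) {
  const int KR = kx * ky * kz * C;
  const long Nout = (long)OX * OY * OZ;
  arma::mat K(Nout, KR, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kk = 0; kk < kz; ++kk)
      for (int kj = 0; kj < ky; ++kj)
        for (int ki = 0; ki < kx; ++ki) {
          double* kc = K.colptr(ki + kx * (kj + ky * (kk + kz * c)));
          // valid ox range: 0 <= ox*stride - pad + ki < X
          int lo = 0;
          while (lo < OX && lo * stride - pad + ki < 0) ++lo;
          int hi = OX;
          while (hi > lo && (hi - 1) * stride - pad + ki >= X) --hi;
          for (int oz = 0; oz < OZ; ++oz) {
            const int iz = oz * stride - pad + kk;
            if (iz < 0 || iz >= Z) continue;
            for (int oy = 0; oy < OY; ++oy) {
              const int iy = oy * stride - pad + kj;
              if (iy < 0 || iy >= Y) continue;
              const double* xp =
                x + (long)X * (iy + (long)Y * (iz + (long)Z * c)) - pad + ki;
              double* dst = kc + (long)OX * (oy + (long)OY * oz);
              if (stride == 1) {
                for (int ox = lo; ox < hi; ++ox) dst[ox] = xp[ox];
              } else {
                for (int ox = lo; ox < hi; ++ox) dst[ox] = xp[ox * stride];
              }
            }
          }
        }
  return K;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int kx = wd[0], ky = wd[1], kz = wd[2], Ci = wd[3], Co = wd[4];
  if (Ci != C) stop("conv3d: input channels (%d) != kernel channels (%d)", C, Ci);
  const int OX = out_extent(X, kx, stride, pad), OY = out_extent(Y, ky, stride, pad),
            OZ = out_extent(Z, kz, stride, pad);
  if (OX < 1 || OY < 1 || OZ < 1) stop("conv3d: kernel larger than padded input");
  arma::mat K = im2col_t(x.begin(), X, Y, Z, C, kx, ky, kz, stride, pad, OX, OY, OZ);
  arma::mat W(const_cast<double*>(w.begin()), kx * ky * kz * Ci, Co, false, true);
  arma::mat O = K * W;                        // Nout x Co
  for (int c = 0; c < Co; ++c) O.col(c) += b[c];
  NumericVector out(O.begin(), O.end());
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, Co);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_backward(NumericVector x, NumericVector w, NumericVector gout,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gout.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int kx = wd[0], ky = wd[1], kz = wd[2], Ci = wd[3], Co = wd[4];
  const int OX = gd[0], OY = gd[1], OZ = gd[2];
  const long Nout = (long)OX * OY * OZ;
  arma::mat K = im2col_t(x.begin(), X, Y, Z, C, kx, ky, kz, stride, pad,
                         OX, OY, OZ);
  arma::mat G(const_cast<double*>(gout.begin()), Nout, Co, false, true);
  arma::mat W(const_cast<double*>(w.begin()), kx * ky * kz * Ci, Co, false, true);

  arma::mat GW = K.t() * G;                   // KR x Co
  arma::vec GB = arma::sum(G, 0).t();
  arma::mat GC = G * W.t();                   // Nout x KR, scatter (col2im)

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  double* gxp = gx.begin();
  for (int c = 0; c < C; ++c)
    for (int kk = 0; kk < kz; ++kk)
      for (int kj = 0; kj < ky; ++kj)
        for (int ki = 0; ki < kx; ++ki) {
          const double* gc = GC.colptr(ki + kx * (kj + ky * (kk + kz * c)));
          int lo = 0;
          while (lo < OX && lo * stride - pad + ki < 0) ++lo;
          int hi = OX;
          while (hi > lo && (hi - 1) * stride - pad + ki >= X) --hi;
          for (int oz = 0; oz < OZ; ++oz) {
            const int iz = oz * stride - pad + kk;
            if (iz < 0 || iz >= Z) continue;
            for (int oy = 0; oy < OY; ++oy) {
              const int iy = oy * stride - pad + kj;
              if (iy < 0 || iy >= Y) continue;
              double* dst =
                gxp + (long)X * (iy + (long)Y * (iz + (long)Z * c)) - pad + ki;
              const double* src = gc + (long)OX * (oy + (long)OY * oz);
              if (stride == 1) {
                for (int ox = lo; ox < hi; ++ox) dst[ox] += src[ox];
              } else {
                for (int ox = lo; ox < hi; ++ox) dst[ox * stride] += src[ox];
              }
            }
          }
        }
  NumericVector gwv(GW.begin(), GW.end());
  gwv.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(GB.begin(), GB.end()));
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerVector kdim, int stride,
                         int pad) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  const int OX = out_extent(X, kx, stride, pad), OY = out_extent(Y, ky, stride, pad),
            OZ = out_extent(Z, kz, stride, pad);
  if (OX < 1 || OY < 1 || OZ < 1) stop("im2col: kernel larger than padded input");
  const long Nout = (long)OX * OY * OZ;
  NumericMatrix K(Nout, kx * ky * kz * C);
  const double* xp0 = x.begin();
  for (int c = 0; c < C; ++c)
    for (int kk = 0; kk < kz; ++kk)
      for (int kj = 0; kj < ky; ++kj)
        for (int ki = 0; ki < kx; ++ki) {
          double* kc = &K(0, ki + kx * (kj + ky * (kk + kz * c)));
          int lo = 0;
          while (lo < OX && lo * stride - pad + ki < 0) ++lo;
          int hi = OX;
          while (hi > lo && (hi - 1) * stride - pad + ki >= X) --hi;
          for (int oz = 0; oz < OZ; ++oz) {
            const int iz = oz * stride - pad + kk;
            if (iz < 0 || iz >= Z) continue;
            for (int oy = 0; oy < OY; ++oy) {
              const int iy = oy * stride - pad + kj;
              if (iy < 0 || iy >= Y) continue;
              const double* xp =
                xp0 + (long)X * (iy + (long)Y * (iz + (long)Z * c)) - pad + ki;
              double* dst = kc + (long)OX * (oy + (long)OY * oz);
              if (stride == 1) {
                for (int ox = lo; ox < hi; ++ox) dst[ox] = xp[ox];
              } else {
                for (int ox = lo; ox < hi; ++ox) dst[ox] = xp[ox * stride];
              }
            }
          }
        }
  K.attr("outdim") = IntegerVector::create(OX, OY, OZ);
  return K;
}

// scatter a (Nout x KR) gradient-of-columns matrix back onto the input grid
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix gc, IntegerVector xdim,
                         IntegerVector kdim, int stride, int pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  const int OX = out_extent(X, kx, stride, pad), OY = out_extent(Y, ky, stride, pad),
            OZ = out_extent(Z, kz, stride, pad);
  NumericVector gx((long)X * Y * Z * C);
  gx.attr("dim") = xdim;
  double* gxp = gx.begin();
  for (int c = 0; c < C; ++c)
    for (int kk = 0; kk < kz; ++kk)
      for (int kj = 0; kj < ky; ++kj)
        for (int ki = 0; ki < kx; ++ki) {
          const double* gcp =
            &gc(0, ki + kx * (kj + ky * (kk + kz * c)));
          int lo = 0;
          while (lo < OX && lo * stride - pad + ki < 0) ++lo;
          int hi = OX;
          while (hi > lo && (hi - 1) * stride - pad + ki >= X) --hi;
          for (int oz = 0; oz < OZ; ++oz) {
            const int iz = oz * stride - pad + kk;
            if (iz < 0 || iz >= Z) continue;
            for (int oy = 0; oy < OY; ++oy) {
              const int iy = oy * stride - pad + kj;
              if (iy < 0 || iy >= Y) continue;
              double* dst =
                gxp + (long)X * (iy + (long)Y * (iz + (long)Z * c)) - pad + ki;
              const double* src = gcp + (long)OX * (oy + (long)OY * oz);
              if (stride == 1) {
                for (int ox = lo; ox < hi; ++ox) dst[ox] += src[ox];
              } else {
                for (int ox = lo; ox < hi; ++ox) dst[ox * stride] += src[ox];
              }
            }
          }
        }
  return gx;
}

static inline int reflect_idx(int i, int n) {
  // reflect without repeating the edge sample (scipy 'mirror' style for n>1)
  if (n == 1) return 0;
  const int period = 2 * (n - 1);
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - i;
}

// Correlate one axis with a symmetric kernel under reflective padding.
static void filter_axis(const std::vector<double>& in, std::vector<double>& out,
                        int X, int Y, int Z, int axis, const arma::vec& k) {
  const int r = ((int)k.n_elem - 1) / 2;
  const int n[3] = {X, Y, Z};
  const long stride[3] = {1, (long)X, (long)X * Y};
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        const int idx3[3] = {x, y, z};
        double acc = 0.0;
        long base = x + (long)X * (y + (long)Y * z) - (long)idx3[axis] * stride[axis];
        for (int t = -r; t <= r; ++t) {
          const int ii = reflect_idx(idx3[axis] + t, n[axis]);
          acc += k[t + r] * in[base + (long)ii * stride[axis]];
        }
        out[x + (long)X * (y + (long)Y * z)] = acc;
      }
}

// radius = 0 truncates at ceil(4 sigma); a positive radius fixes the
// half-width (e.g. 5 for an 11-wide SSIM window)
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector x, NumericVector sigma_vox,
                          int radius = 0) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2];
  std::vector<double> a(x.begin(), x.end()), b(a.size());
  for (int axis = 0; axis < 3; ++axis) {
    const double s = sigma_vox[axis];
    if (s <= 0) continue;
    const int r = (radius > 0) ? radius : std::max(1, (int)std::ceil(4.0 * s));
    arma::vec k(2 * r + 1);
    for (int t = -r; t <= r; ++t) k[t + r] = std::exp(-0.5 * t * t / (s * s));
    k /= arma::accu(k);
    filter_axis(a, b, X, Y, Z, axis, k);
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = xd;
  return out;
}

// Per-channel sliding-window box sum with zero padding (symmetric, hence
// self-adjoint). The local mean divides by the per-voxel count of valid
// window positions, so a constant map stays constant at the boundary.
// [[Rcpp::export]]
NumericVector cpp_box_sum3d(NumericVector x, int w) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = (xd.size() == 4) ? xd[3] : 1;
  const int r = (w - 1) / 2;
  const long nvox = (long)X * Y * Z;
  NumericVector out(x.size());
  out.attr("dim") = xd;
  std::vector<double> tmp1(nvox), tmp2(nvox);
  for (int c = 0; c < C; ++c) {
    const double* xp = x.begin() + c * nvox;
    double* op = out.begin() + c * nvox;
    // axis x
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y)
        for (int i = 0; i < X; ++i) {
          double acc = 0;
          for (int t = std::max(0, i - r); t <= std::min(X - 1, i + r); ++t)
            acc += xp[t + (long)X * (y + (long)Y * z)];
          tmp1[i + (long)X * (y + (long)Y * z)] = acc;
        }
    // axis y
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y)
        for (int i = 0; i < X; ++i) {
          double acc = 0;
          for (int t = std::max(0, y - r); t <= std::min(Y - 1, y + r); ++t)
            acc += tmp1[i + (long)X * (t + (long)Y * z)];
          tmp2[i + (long)X * (y + (long)Y * z)] = acc;
        }
    // axis z
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y)
        for (int i = 0; i < X; ++i) {
          double acc = 0;
          for (int t = std::max(0, z - r); t <= std::min(Z - 1, z + r); ++t)
            acc += tmp2[i + (long)X * (y + (long)Y * t)];
          op[i + (long)X * (y + (long)Y * z)] = acc;
        }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector x, IntegerVector tshape) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int TX = tshape[0], TY = tshape[1], TZ = tshape[2];
  NumericVector out((long)TX * TY * TZ);
  out.attr("dim") = IntegerVector::create(TX, TY, TZ);
  const double sx = (double)X / TX, sy = (double)Y / TY, sz = (double)Z / TZ;
  const double* xp = x.begin();
  double* op = out.begin();
  for (int k = 0; k < TZ; ++k) {
    double fz = (k + 0.5) * sz - 0.5;
    int z0 = (int)std::floor(fz); double wz = fz - z0;
    int z0c = std::min(std::max(z0, 0), Z - 1), z1c = std::min(std::max(z0 + 1, 0), Z - 1);
    for (int j = 0; j < TY; ++j) {
      double fy = (j + 0.5) * sy - 0.5;
      int y0 = (int)std::floor(fy); double wy = fy - y0;
      int y0c = std::min(std::max(y0, 0), Y - 1), y1c = std::min(std::max(y0 + 1, 0), Y - 1);
      for (int i = 0; i < TX; ++i) {
        double fx = (i + 0.5) * sx - 0.5;
        int x0 = (int)std::floor(fx); double wx = fx - x0;
        int x0c = std::min(std::max(x0, 0), X - 1), x1c = std::min(std::max(x0 + 1, 0), X - 1);
        #define V(a, b, c) xp[(a) + (long)X * ((b) + (long)Y * (c))]
        double v =
          (1 - wz) * ((1 - wy) * ((1 - wx) * V(x0c, y0c, z0c) + wx * V(x1c, y0c, z0c)) +
                      wy       * ((1 - wx) * V(x0c, y1c, z0c) + wx * V(x1c, y1c, z0c))) +
          wz       * ((1 - wy) * ((1 - wx) * V(x0c, y0c, z1c) + wx * V(x1c, y0c, z1c)) +
                      wy       * ((1 - wx) * V(x0c, y1c, z1c) + wx * V(x1c, y1c, z1c)));
        #undef V
        op[i + (long)TX * (j + (long)TY * k)] = v;
      }
    }
  }
  return out;
}

// 6-connected component labelling of a logical mask; labels 1..n by discovery.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask) {
  IntegerVector xd = mask.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const long n = (long)X * Y * Z;
  IntegerVector lab(n);
  lab.attr("dim") = xd;
  int next = 0;
  const int dx[6] = {1, -1, 0, 0, 0, 0}, dy[6] = {0, 0, 1, -1, 0, 0},
            dz[6] = {0, 0, 0, 0, 1, -1};
  std::queue<long> q;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      long v = q.front(); q.pop();
      int x = v % X, y = (v / X) % Y, z = v / ((long)X * Y);
      for (int d = 0; d < 6; ++d) {
        int nx = x + dx[d], ny = y + dy[d], nz = z + dz[d];
        if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
        long u = nx + (long)X * (ny + (long)Y * nz);
        if (mask[u] && !lab[u]) { lab[u] = next; q.push(u); }
      }
    }
  }
  return lab;
}
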