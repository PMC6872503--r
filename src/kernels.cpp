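#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Column-major linear index for a [X,Y,Z,C] array.
static inline int idx4(int x, int y, int z, int c, int X, int Y, int Z) {
  return x + X * (y + Y * (z + (long long)Z * c));
}

static inline int out_len(int n, int k, int s, bool same) {
  if (same) return (n + s - 1) / s;            // ceil(n/s)
  return (n - k) / s + 1;                       // valid
}

static inline int pad_before(int n, int k, int s, bool same) {
  if (!same) return 0;
  int o = (n + s - 1) / s;
  int pad = (o - 1) * s + k - n;
  if (pad < 0) pad = 0;
  return pad / 2;
}

// 3D convolution forward pass. x: [X,Y,Z,Cin], w: [K,K,K,Cin,Cout], b: [Cout].
// Returns the pre-activation output [OX,OY,OZ,Cout].
// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector b,
                         int sx, int sy, int sz, bool same) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int K = wdim[0], Cout = wdim[4];
  const int OX = out_len(X, K, sx, same), OY = out_len(Y, K, sy, same),
            OZ = out_len(Z, K, sz, same);
  const int px = pad_before(X, K, sx, same), py = pad_before(Y, K, sy, same),
            pz = pad_before(Z, K, sz, same);
  NumericVector out((long long)OX * OY * OZ * Cout);
  const double *xp = x.begin(), *wp = w.begin();
  double *op = out.begin();
  const long long wstride_ci = (long long)K * K * K;
  const long long wstride_co = wstride_ci * Cin;
  for (int co = 0; co < Cout; ++co) {
    for (int oz = 0; oz < OZ; ++oz) {
      const int z0 = oz * sz - pz;
      for (int oy = 0; oy < OY; ++oy) {
        const int y0 = oy * sy - py;
        for (int ox = 0; ox < OX; ++ox) {
          const int x0 = ox * sx - px;
          double acc = b[co];
          for (int ci = 0; ci < Cin; ++ci) {
            const double *wb = wp + co * wstride_co + ci * wstride_ci;
            for (int kz = 0; kz < K; ++kz) {
              const int zz = z0 + kz; if (zz < 0 || zz >= Z) continue;
              for (int ky = 0; ky < K; ++ky) {
                const int yy = y0 + ky; if (yy < 0 || yy >= Y) continue;
                const double *xrow = xp + idx4(0, yy, zz, ci, X, Y, Z);
                const double *wrow = wb + K * (ky + K * kz);
                for (int kx = 0; kx < K; ++kx) {
                  const int xx = x0 + kx; if (xx < 0 || xx >= X) continue;
                  acc += xrow[xx] * wrow[kx];
                }
              }
            }
          }
          op[idx4(ox, oy, oz, co, OX, OY, OZ)] = acc;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, Cout);
  return out;
}

// Backward pass of conv3d_fwd. gout is the gradient w.r.t. the pre-activation.
// Returns grad wrt input, weights and bias.
// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, IntegerVector xdim,
                NumericVector w, IntegerVector wdim,
                NumericVector gout,
                int sx, int sy, int sz, bool same) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int K = wdim[0], Cout = wdim[4];
  const int OX = out_len(X, K, sx, same), OY = out_len(Y, K, sy, same),
            OZ = out_len(Z, K, sz, same);
  const int px = pad_before(X, K, sx, same), py = pad_before(Y, K, sy, same),
            pz = pad_before(Z, K, sz, same);
  NumericVector gx((long long)X * Y * Z * Cin);
  NumericVector gw(w.size());
  NumericVector gb(Cout);
  const double *xp = x.begin(), *wp = w.begin(), *gp = gout.begin();
  double *gxp = gx.begin(), *gwp = gw.begin();
  const long long wstride_ci = (long long)K * K * K;
  const long long wstride_co = wstride_ci * Cin;
  for (int co = 0; co < Cout; ++co) {
    for (int oz = 0; oz < OZ; ++oz) {
      const int z0 = oz * sz - pz;
      for (int oy = 0; oy < OY; ++oy) {
        const int y0 = oy * sy - py;
        for (int ox = 0; ox < OX; ++ox) {
          const int x0 = ox * sx - px;
          const double g = gp[idx4(ox, oy, oz, co, OX, OY, OZ)];
          if (g == 0.0) continue;
          gb[co] += g;
          for (int ci = 0; ci < Cin; ++ci) {
            const double *wb = wp + co * wstride_co + ci * wstride_ci;
            double *gwb = gwp + co * wstride_co + ci * wstride_ci;
            for (int kz = 0; kz < K; ++kz) {
              const int zz = z0 + kz; if (zz < 0 || zz >= Z) continue;
              for (int ky = 0; ky < K; ++ky) {
                const int yy = y0 + ky; if (yy < 0 || yy >= Y) continue;
                const long long base = idx4(0, yy, zz, ci, X, Y, Z);
                const int wbase = K * (ky + K * kz);
                for (int kx = 0; kx < K; ++kx) {
                  const int xx = x0 + kx; if (xx < 0 || xx >= X) continue;
                  gwb[wbase + kx] += g * xp[base + xx];
                  gxp[base + xx] += g * wb[wbase + kx];
                }
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling, stride 2, optional ceil-mode partial windows at borders.
// Returns pooled array and 1-based argmax positions into the input.
// [[Rcpp::export(name = ".maxpool3d_fwd")]]
List maxpool3d_fwd(NumericVector x, IntegerVector xdim, bool ceil_mode) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int OX = ceil_mode ? (X + 1) / 2 : X / 2;
  const int OY = ceil_mode ? (Y + 1) / 2 : Y / 2;
  const int OZ = ceil_mode ? (Z + 1) / 2 : Z / 2;
  NumericVector out((long long)OX * OY * OZ * C);
  IntegerVector arg(out.size());
  const double *xp = x.begin();
  for (int c = 0; c < C; ++c)
    for (int oz = 0; oz < OZ; ++oz)
      for (int oy = 0; oy < OY; ++oy)
        for (int ox = 0; ox < OX; ++ox) {
          double best = R_NegInf; int besti = -1;
          for (int dz = 0; dz < 2; ++dz) {
            const int zz = 2 * oz + dz; if (zz >= Z) continue;
            for (int dy = 0; dy < 2; ++dy) {
              const int yy = 2 * oy + dy; if (yy >= Y) continue;
              for (int dx = 0; dx < 2; ++dx) {
                const int xx = 2 * ox + dx; if (xx >= X) continue;
                const int ii = idx4(xx, yy, zz, c, X, Y, Z);
                if (xp[ii] > best) { best = xp[ii]; besti = ii; }
              }
            }
          }
          const int oi = idx4(ox, oy, oz, c, OX, OY, OZ);
          out[oi] = best;
          arg[oi] = besti + 1;
        }
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, C);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool3d_bwd")]]
NumericVector maxpool3d_bwd(IntegerVector argmax, NumericVector gout,
                            IntegerVector xdim) {
  NumericVector gx((long long)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[argmax[i] - 1] += gout[i];
  gx.attr("dim") = xdim;
  return gx;
}

// Separable 1D convolution along one axis of a 3D array with a symmetric
// kernel; weights falling outside the array are dropped and the remaining
// window renormalised (so constant images stay constant).
// [[Rcpp::export(name = ".conv1d_axis")]]
NumericVector conv1d_axis(NumericVector x, IntegerVector dim3,
                          NumericVector kernel, int axis) {
  const int X = dim3[0], Y = dim3[1], Z = dim3[2];
  const int K = kernel.size(), H = K / 2;
  NumericVector out((long long)X * Y * Z);
  const double *xp = x.begin(); double *op = out.begin();
  const int n[3] = {X, Y, Z};
  const int len = n[axis];
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int xx = 0; xx < X; ++xx) {
        const int pos[3] = {xx, y, z};
        double acc = 0.0, wsum = 0.0;
        for (int k = 0; k < K; ++k) {
          const int p = pos[axis] + k - H;
          if (p < 0 || p >= len) continue;
          int q[3] = {xx, y, z}; q[axis] = p;
          acc += kernel[k] * xp[q[0] + X * (q[1] + (long long)Y * q[2])];
          wsum += kernel[k];
        }
        op[xx + X * (y + (long long)Y * z)] = acc / wsum;
      }
  out.attr("dim") = dim3;
  return out;
}

// Connected components of a 3D logical mask under 6- or 26-connectivity.
// Returns integer labels (0 = background), numbered in scan order.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dim3,
                               int connectivity) {
  const int X = dim3[0], Y = dim3[1], Z = dim3[2];
  const long long N = (long long)X * Y * Z;
  IntegerVector lab(N);
  int next = 0;
  std::queue<long long> q;
  for (long long s = 0; s < N; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      const long long cur = q.front(); q.pop();
      const int cx = cur % X, cy = (cur / X) % Y, cz = cur / ((long long)X * Y);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1)
              continue;
            const int nx = cx + dx, ny = cy + dy, nz = cz + dz;
            if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z)
              continue;
            const long long ni = nx + X * (ny + (long long)Y * nz);
            if (mask[ni] && lab[ni] == 0) { lab[ni] = next; q.push(ni); }
          }
    }
  }
  lab.attr("dim") = dim3;
  return lab;
}
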