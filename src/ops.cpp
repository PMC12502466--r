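#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Column-major voxel index helpers. Grids are axis-aligned: physical
// coordinate of voxel (i,j,k) is origin + index * spacing (0-based indices).

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Resample `vol` onto a target grid through a fixed->moving physical map
// given as a row-major 4x4 matrix (last row 0001 assumed). Out-of-field
// voxels are set to 0. interp: 0 = nearest, 1 = trilinear.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dim,
                           NumericVector spacing, NumericVector origin,
                           IntegerVector odim, NumericVector ospacing,
                           NumericVector oorigin, NumericVector fix2mov,
                           int interp) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out(ox * oy * oz);
  const double *m = fix2mov.begin();
  for (int k = 0; k < oz; ++k) {
    double pz = oorigin[2] + k * ospacing[2];
    for (int j = 0; j < oy; ++j) {
      double py = oorigin[1] + j * ospacing[1];
      for (int i = 0; i < ox; ++i) {
        double px = oorigin[0] + i * ospacing[0];
        // physical point in moving space
        double qx = m[0] * px + m[1] * py + m[2] * pz + m[3];
        double qy = m[4] * px + m[5] * py + m[6] * pz + m[7];
        double qz = m[8] * px + m[9] * py + m[10] * pz + m[11];
        // continuous voxel index in moving grid
        double u = (qx - origin[0]) / spacing[0];
        double v = (qy - origin[1]) / spacing[1];
        double w = (qz - origin[2]) / spacing[2];
        double val = 0.0;
        if (interp == 0) {
          int iu = (int)std::lround(u), iv = (int)std::lround(v),
              iw = (int)std::lround(w);
          if (iu >= 0 && iu < nx && iv >= 0 && iv < ny && iw >= 0 && iw < nz)
            val = vol[idx3(iu, iv, iw, nx, ny)];
        } else {
          int i0 = (int)std::floor(u), j0 = (int)std::floor(v),
              k0 = (int)std::floor(w);
          double fu = u - i0, fv = v - j0, fw = w - k0;
          if (i0 >= 0 && i0 + 1 < nx && j0 >= 0 && j0 + 1 < ny && k0 >= 0 &&
              k0 + 1 < nz) {
            double c00 = vol[idx3(i0, j0, k0, nx, ny)] * (1 - fu) +
                         vol[idx3(i0 + 1, j0, k0, nx, ny)] * fu;
            double c10 = vol[idx3(i0, j0 + 1, k0, nx, ny)] * (1 - fu) +
                         vol[idx3(i0 + 1, j0 + 1, k0, nx, ny)] * fu;
            double c01 = vol[idx3(i0, j0, k0 + 1, nx, ny)] * (1 - fu) +
                         vol[idx3(i0 + 1, j0, k0 + 1, nx, ny)] * fu;
            double c11 = vol[idx3(i0, j0 + 1, k0 + 1, nx, ny)] * (1 - fu) +
                         vol[idx3(i0 + 1, j0 + 1, k0 + 1, nx, ny)] * fu;
            val = (c00 * (1 - fv) + c10 * fv) * (1 - fw) +
                  (c01 * (1 - fv) + c11 * fv) * fw;
          } else if (i0 >= -1 && i0 < nx && j0 >= -1 && j0 < ny && k0 >= -1 &&
                     k0 < nz) {
            // border: trilinear with zero outside the field of view
            double acc = 0.0;
            for (int dk = 0; dk <= 1; ++dk)
              for (int dj = 0; dj <= 1; ++dj)
                for (int di = 0; di <= 1; ++di) {
                  int ii = i0 + di, jj = j0 + dj, kk = k0 + dk;
                  if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 ||
                      kk >= nz)
                    continue;
                  double wgt = (di ? fu : 1 - fu) * (dj ? fv : 1 - fv) *
                               (dk ? fw : 1 - fw);
                  acc += wgt * vol[idx3(ii, jj, kk, nx, ny)];
                }
            val = acc;
          }
        }
        out[idx3(i, j, k, ox, oy)] = val;
      }
    }
  }
  return out;
}

// Separable 1D convolution along `axis` (0,1,2) with a symmetric kernel,
// border handled by renormalizing over the in-bounds taps.
// [[Rcpp::export]]
NumericVector cpp_filter1d(NumericVector vol, IntegerVector dim,
                           NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kh = (kernel.size() - 1) / 2;
  NumericVector out(vol.size());
  int n[3] = {nx, ny, nz};
  int stride[3] = {1, nx, nx * ny};
  int na = n[axis], sa = stride[axis];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int pos[3] = {i, j, k};
        int base = idx3(i, j, k, nx, ny);
        double acc = 0.0, wsum = 0.0;
        int a = pos[axis];
        for (int t = -kh; t <= kh; ++t) {
          int aa = a + t;
          if (aa < 0 || aa >= na) continue;
          double w = kernel[t + kh];
          acc += w * vol[base + (aa - a) * sa];
          wsum += w;
        }
        out[base] = wsum > 0 ? acc / wsum : 0.0;
      }
  return out;
}

// 3x3x3 convolution, zero padding 1, stride 1.
// The interior is computed in one fused pass per (ci,co) pair (all 27 taps
// accumulated row-wise, vectorizable over the contiguous x index); border
// voxels fall back to a bounds-checked loop. `flip` mirrors the kernel,
// which turns the same routine into the input-gradient (transposed) conv.
static void conv3_accum(double *__restrict__ yo,
                        const double *__restrict__ xi, const double *wk,
                        int nx, int ny, int nz, bool flip) {
  double w[27];
  for (int t = 0; t < 27; ++t) w[t] = flip ? wk[26 - t] : wk[t];
  // interior rows: k,j in [1, n-2], i in [1, nx-2]. Each output row is
  // accumulated in a local buffer via 27 row-local AXPY passes; the source
  // rows stay in L1, and the simple shifted loops vectorize.
  std::vector<double> buf(nx);
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j) {
      double *yr = yo + nx * (j + ny * k);
      std::fill(buf.begin(), buf.end(), 0.0);
      double *__restrict__ bp = buf.data();
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj) {
          const double *__restrict__ xr =
              xi + nx * ((j + dj) + ny * (k + dk));
          const double *wm = w + 3 * ((dj + 1) + 3 * (dk + 1));
          const double w0 = wm[0], w1 = wm[1], w2 = wm[2];
          for (int i = 1; i < nx - 1; ++i)
            bp[i] += w0 * xr[i - 1] + w1 * xr[i] + w2 * xr[i + 1];
        }
      for (int i = 1; i < nx - 1; ++i) yr[i] += bp[i];
    }
  // border voxels: bounds-checked accumulation
  for (int k = 0; k < nz; ++k) {
    bool bk = (k == 0 || k == nz - 1);
    for (int j = 0; j < ny; ++j) {
      bool bj = (j == 0 || j == ny - 1);
      for (int i = 0; i < nx; ++i) {
        if (!bk && !bj && i != 0 && i != nx - 1) {
          if (j > 0 && j < ny - 1 && k > 0 && k < nz - 1) { i = nx - 2; continue; }
        }
        double acc = 0.0;
        for (int dk = -1; dk <= 1; ++dk) {
          int kk = k + dk;
          if (kk < 0 || kk >= nz) continue;
          for (int dj = -1; dj <= 1; ++dj) {
            int jj = j + dj;
            if (jj < 0 || jj >= ny) continue;
            const double *xr = xi + nx * (jj + ny * kk);
            const double *wm = w + 3 * ((dj + 1) + 3 * (dk + 1));
            for (int di = -1; di <= 1; ++di) {
              int ii = i + di;
              if (ii < 0 || ii >= nx) continue;
              acc += wm[di + 1] * xr[ii];
            }
          }
        }
        yo[i + nx * (j + ny * k)] += acc;
      }
    }
  }
}

// x: (nx,ny,nz,cin) column-major; w: (3,3,3,cin,cout); b: (cout).
// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, IntegerVector dim, int cin,
                            NumericVector w, NumericVector b, int cout) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nvox = nx * ny * nz;
  NumericVector y(nvox * (size_t)cout);
  for (int co = 0; co < cout; ++co) {
    double *yo = y.begin() + (size_t)co * nvox;
    for (int v = 0; v < nvox; ++v) yo[v] = b[co];
    for (int ci = 0; ci < cin; ++ci)
      conv3_accum(yo, x.begin() + (size_t)ci * nvox,
                  w.begin() + 27 * (ci + (size_t)cin * co), nx, ny, nz,
                  false);
  }
  return y;
}

// Gradient of the 3x3x3 conv wrt its input: correlation with the flipped
// kernel, gx(p) = sum_d w(d) gy(p - (d-1)).
// [[Rcpp::export]]
NumericVector cpp_conv3_bwd_input(NumericVector gy, IntegerVector dim, int cin,
                                  NumericVector w, int cout) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nvox = nx * ny * nz;
  NumericVector gx(nvox * (size_t)cin);
  for (int ci = 0; ci < cin; ++ci) {
    double *gxi = gx.begin() + (size_t)ci * nvox;
    for (int co = 0; co < cout; ++co)
      conv3_accum(gxi, gy.begin() + (size_t)co * nvox,
                  w.begin() + 27 * (ci + (size_t)cin * co), nx, ny, nz,
                  true);
  }
  return gx;
}

// Gradients of the 3x3x3 conv wrt weights and bias; returns c(gw, gb).
// Reductions use four accumulators to break the add dependency chain.
// [[Rcpp::export]]
NumericVector cpp_conv3_bwd_w(NumericVector x, NumericVector gy,
                              IntegerVector dim, int cin, int cout) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nvox = nx * ny * nz;
  NumericVector g(27 * (size_t)cin * cout + cout);
  double *gw = g.begin();
  double *gb = g.begin() + 27 * (size_t)cin * cout;
  for (int co = 0; co < cout; ++co) {
    const double *gyo = gy.begin() + (size_t)co * nvox;
    double s0 = 0, s1 = 0, s2 = 0, s3 = 0;
    int v = 0;
    for (; v + 3 < nvox; v += 4) {
      s0 += gyo[v]; s1 += gyo[v + 1]; s2 += gyo[v + 2]; s3 += gyo[v + 3];
    }
    for (; v < nvox; ++v) s0 += gyo[v];
    gb[co] = s0 + s1 + s2 + s3;
    for (int ci = 0; ci < cin; ++ci) {
      const double *xi = x.begin() + (size_t)ci * nvox;
      double *gwk = gw + 27 * (ci + (size_t)cin * co);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            double a0 = 0, a1 = 0, a2 = 0, a3 = 0;
            const int k0 = std::max(0, -dk), k1 = std::min(nz, nz - dk);
            const int j0 = std::max(0, -dj), j1 = std::min(ny, ny - dj);
            const int i0 = std::max(0, -di), i1 = std::min(nx, nx - di);
            for (int k = k0; k < k1; ++k)
              for (int j = j0; j < j1; ++j) {
                const double *xr = xi + nx * ((j + dj) + ny * (k + dk)) + di;
                const double *gr = gyo + nx * (j + ny * k);
                int i = i0;
                for (; i + 3 < i1; i += 4) {
                  a0 += xr[i] * gr[i];
                  a1 += xr[i + 1] * gr[i + 1];
                  a2 += xr[i + 2] * gr[i + 2];
                  a3 += xr[i + 3] * gr[i + 3];
                }
                for (; i < i1; ++i) a0 += xr[i] * gr[i];
              }
            gwk[(di + 1) + 3 * ((dj + 1) + 3 * (dk + 1))] = a0 + a1 + a2 + a3;
          }
    }
  }
  return g;
}

// Row-wise softmax over an (n x C) matrix of logits.
// [[Rcpp::export]]
NumericVector cpp_softmax(NumericVector z, int n, int C) {
  NumericVector p(z.size());
  for (int i = 0; i < n; ++i) {
    double mx = z[i];
    for (int c = 1; c < C; ++c) mx = std::max(mx, z[i + (size_t)c * n]);
    double s = 0.0;
    for (int c = 0; c < C; ++c) {
      double e = std::exp(z[i + (size_t)c * n] - mx);
      p[i + (size_t)c * n] = e;
      s += e;
    }
    for (int c = 0; c < C; ++c) p[i + (size_t)c * n] /= s;
  }
  return p;
}

// Soft-Dice + one-vs-rest BCE loss on class probabilities p vs (soft)
// one-hot targets t, and its gradient pushed through the softmax, i.e.
// wrt the logits. Returns c(loss, g_logits). `w` scales the gradient
// (deep-supervision level weight).
// [[Rcpp::export]]
NumericVector cpp_dice_bce_softmax_grad(NumericVector p, NumericVector t,
                                        int n, int C, double w) {
  const double eps = 1e-5, clip = 1e-7;
  std::vector<double> inter(C, 0.0), sp(C, 0.0), st(C, 0.0);
  for (int c = 0; c < C; ++c) {
    const double *pc = p.begin() + (size_t)c * n;
    const double *tc = t.begin() + (size_t)c * n;
    double a = 0, b = 0, d = 0;
    for (int i = 0; i < n; ++i) {
      a += pc[i] * tc[i];
      b += pc[i];
      d += tc[i];
    }
    inter[c] = a; sp[c] = b; st[c] = d;
  }
  double dice_loss = 0.0, bce = 0.0;
  std::vector<double> denom(C), num(C);
  for (int c = 0; c < C; ++c) {
    denom[c] = sp[c] + st[c] + eps;
    num[c] = 2.0 * inter[c] + eps;
    dice_loss += 1.0 - num[c] / denom[c];
  }
  dice_loss /= C;
  NumericVector out(1 + p.size());
  double *g = out.begin() + 1;
  // gradient wrt probabilities: dice + bce terms
  for (int c = 0; c < C; ++c) {
    const double *pc_ = p.begin() + (size_t)c * n;
    const double *tc = t.begin() + (size_t)c * n;
    double *gc = g + (size_t)c * n;
    const double d2 = denom[c] * denom[c];
    for (int i = 0; i < n; ++i) {
      double pv = std::min(1.0 - clip, std::max(clip, pc_[i]));
      bce += -(tc[i] * std::log(pv) + (1.0 - tc[i]) * std::log(1.0 - pv));
      double gd = -(2.0 * tc[i] * denom[c] - num[c]) / d2 / C;
      double gb = (-tc[i] / pv + (1.0 - tc[i]) / (1.0 - pv)) /
                  ((double)n * C);
      gc[i] = gd + gb;
    }
  }
  bce /= (double)n * C;
  // push through the softmax: g_z = p * (g - sum_c g_c p_c), scaled by w
  for (int i = 0; i < n; ++i) {
    double dot = 0.0;
    for (int c = 0; c < C; ++c)
      dot += g[i + (size_t)c * n] * p[i + (size_t)c * n];
    for (int c = 0; c < C; ++c) {
      size_t ix = i + (size_t)c * n;
      g[ix] = w * p[ix] * (g[ix] - dot);
    }
  }
  out[0] = dice_loss + bce;
  return out;
}
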