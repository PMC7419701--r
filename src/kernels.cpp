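#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Zero-phase IIR filtering (forward-backward), matrix columns = voxel series.
// Direct form II transposed; initial state zi scaled by the first sample of
// the (odd-reflection) padded series, so step transients are absorbed.
// ---------------------------------------------------------------------------

static void df2t_filter(const std::vector<double>& b, const std::vector<double>& a,
                        std::vector<double>& x, const std::vector<double>& zi) {
  const int n = (int)x.size();
  const int m = (int)zi.size();
  std::vector<double> z(m);
  for (int j = 0; j < m; ++j) z[j] = zi[j] * x[0];
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int j = 0; j < m - 1; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    z[m - 1] = b[m] * xi - a[m] * yi;
    x[i] = yi;
  }
}

// [[Rcpp::export(name = ".filtfilt_mat_cpp")]]
NumericMatrix filtfilt_mat_cpp(NumericVector b, NumericVector a,
                               NumericMatrix X, NumericVector zi) {
  const int T = X.nrow(), V = X.ncol();
  const int nf = std::max(b.size(), a.size());
  const int npad = std::min(T - 1, 3 * (nf - 1));
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  bb.resize(nf, 0.0); aa.resize(nf, 0.0);
  std::vector<double> zz(zi.begin(), zi.end());
  NumericMatrix out(T, V);
  std::vector<double> ext(T + 2 * npad);
  for (int v = 0; v < V; ++v) {
    const double* x = &X(0, v);
    // odd reflection padding at both ends
    for (int i = 0; i < npad; ++i) ext[i] = 2.0 * x[0] - x[npad - i];
    for (int i = 0; i < T; ++i) ext[npad + i] = x[i];
    for (int i = 0; i < npad; ++i) ext[npad + T + i] = 2.0 * x[T - 1] - x[T - 2 - i];
    df2t_filter(bb, aa, ext, zz);
    std::reverse(ext.begin(), ext.end());
    df2t_filter(bb, aa, ext, zz);
    std::reverse(ext.begin(), ext.end());
    for (int i = 0; i < T; ++i) out(i, v) = ext[npad + i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable 3D convolution with symmetric (half-sample reflection) boundaries.
// arr is a stack of nvol volumes of shape d1 x d2 x d3; each axis kernel is a
// normalized symmetric vector (odd length). Conserves total intensity.
// ---------------------------------------------------------------------------

static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static void conv_axis(std::vector<double>& src, std::vector<double>& dst,
                      int d1, int d2, int d3, int axis,
                      const std::vector<double>& k) {
  const int r = ((int)k.size() - 1) / 2;
  const int n = (axis == 0) ? d1 : (axis == 1) ? d2 : d3;
  const R_xlen_t s1 = 1, s2 = d1, s3 = (R_xlen_t)d1 * d2;
  const R_xlen_t stride = (axis == 0) ? s1 : (axis == 1) ? s2 : s3;
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) {
        const int pos = (axis == 0) ? x : (axis == 1) ? y : z;
        const R_xlen_t base = x * s1 + y * s2 + z * s3;
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int p = reflect_idx(pos + t, n);
          acc += k[t + r] * src[base + (R_xlen_t)(p - pos) * stride];
        }
        dst[base] = acc;
      }
}

// [[Rcpp::export(name = ".sepconv3d_cpp")]]
NumericVector sepconv3d_cpp(NumericVector arr, int d1, int d2, int d3, int nvol,
                            List kernels) {
  const R_xlen_t vsz = (R_xlen_t)d1 * d2 * d3;
  NumericVector out = clone(arr);
  std::vector<double> buf(vsz), tmp(vsz);
  for (int v = 0; v < nvol; ++v) {
    std::copy(out.begin() + v * vsz, out.begin() + (v + 1) * vsz, buf.begin());
    for (int axis = 0; axis < 3; ++axis) {
      RObject ko = kernels[axis];
      if (ko.isNULL()) continue;
      NumericVector kv(ko);
      if (kv.size() <= 1) continue;
      std::vector<double> k(kv.begin(), kv.end());
      conv_axis(buf, tmp, d1, d2, d3, axis, k);
      std::swap(buf, tmp);
    }
    std::copy(buf.begin(), buf.end(), out.begin() + v * vsz);
  }
  return out;
}

// ---------------------------------------------------------------------------
// 3D convolution for the classifier: zero padding, stride 1, cubic kernels.
// input [nx,ny,nz,Cin,N], weights [k,k,k,Cin,Cout], bias [Cout].
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".conv3d_fwd_cpp")]]
NumericVector conv3d_fwd_cpp(NumericVector input, IntegerVector idim,
                             NumericVector weight, int k,
                             NumericVector bias) {
  const int nx = idim[0], ny = idim[1], nz = idim[2], Ci = idim[3], N = idim[4];
  const int Co = bias.size();
  const int r = (k - 1) / 2;
  const R_xlen_t vs = (R_xlen_t)nx * ny * nz;
  NumericVector out((R_xlen_t)vs * Co * N);
  const double* in = input.begin();
  const double* W = weight.begin();
  double* o = out.begin();
  const R_xlen_t wci = (R_xlen_t)k * k * k;           // stride per Cin in W
  const R_xlen_t wco = wci * Ci;                      // stride per Cout in W
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      double* op = o + ((R_xlen_t)n * Co + co) * vs;
      const double bv = bias[co];
      for (R_xlen_t i = 0; i < vs; ++i) op[i] = bv;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* ip = in + ((R_xlen_t)n * Ci + ci) * vs;
        const double* wp = W + (R_xlen_t)co * wco + (R_xlen_t)ci * wci;
        for (int kz = -r; kz <= r; ++kz)
          for (int ky = -r; ky <= r; ++ky)
            for (int kx = -r; kx <= r; ++kx) {
              const double w = wp[(kx + r) + k * ((ky + r) + k * (kz + r))];
              if (w == 0.0) continue;
              const int zlo = std::max(0, -kz), zhi = std::min(nz, nz - kz);
              const int ylo = std::max(0, -ky), yhi = std::min(ny, ny - ky);
              const int xlo = std::max(0, -kx), xhi = std::min(nx, nx - kx);
              for (int z = zlo; z < zhi; ++z)
                for (int y = ylo; y < yhi; ++y) {
                  double* orow = op + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
                  const double* irow = ip + (R_xlen_t)(kx) +
                    (R_xlen_t)nx * ((y + ky) + (R_xlen_t)ny * (z + kz));
                  for (int x = xlo; x < xhi; ++x)
                    orow[x] += w * irow[x];
                }
            }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, Co, N);
  return out;
}

// [[Rcpp::export(name = ".conv3d_bwd_cpp")]]
List conv3d_bwd_cpp(NumericVector input, IntegerVector idim,
                    NumericVector weight, int k, int Co,
                    NumericVector gout) {
  const int nx = idim[0], ny = idim[1], nz = idim[2], Ci = idim[3], N = idim[4];
  const int r = (k - 1) / 2;
  const R_xlen_t vs = (R_xlen_t)nx * ny * nz;
  NumericVector gin((R_xlen_t)vs * Ci * N);
  NumericVector gw((R_xlen_t)k * k * k * Ci * Co);
  NumericVector gb(Co);
  const double* in = input.begin();
  const double* W = weight.begin();
  const double* go = gout.begin();
  const R_xlen_t wci = (R_xlen_t)k * k * k;
  const R_xlen_t wco = wci * Ci;
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      const double* gop = go + ((R_xlen_t)n * Co + co) * vs;
      double acc_b = 0.0;
      for (R_xlen_t i = 0; i < vs; ++i) acc_b += gop[i];
      gb[co] += acc_b;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* ip = in + ((R_xlen_t)n * Ci + ci) * vs;
        double* gip = gin.begin() + ((R_xlen_t)n * Ci + ci) * vs;
        const double* wp = W + (R_xlen_t)co * wco + (R_xlen_t)ci * wci;
        double* gwp = gw.begin() + (R_xlen_t)co * wco + (R_xlen_t)ci * wci;
        for (int kz = -r; kz <= r; ++kz)
          for (int ky = -r; ky <= r; ++ky)
            for (int kx = -r; kx <= r; ++kx) {
              const R_xlen_t wid = (kx + r) + k * ((ky + r) + k * (kz + r));
              const double w = wp[wid];
              double acc_w = 0.0;
              const int zlo = std::max(0, -kz), zhi = std::min(nz, nz - kz);
              const int ylo = std::max(0, -ky), yhi = std::min(ny, ny - ky);
              const int xlo = std::max(0, -kx), xhi = std::min(nx, nx - kx);
              for (int z = zlo; z < zhi; ++z)
                for (int y = ylo; y < yhi; ++y) {
                  const double* grow = gop + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
                  const R_xlen_t ioff = (R_xlen_t)(kx) +
                    (R_xlen_t)nx * ((y + ky) + (R_xlen_t)ny * (z + kz));
                  const double* irow = ip + ioff;
                  double* girow = gip + ioff;
                  for (int x = xlo; x < xhi; ++x) {
                    const double g = grow[x];
                    acc_w += irow[x] * g;
                    girow[x] += w * g;
                  }
                }
              gwp[wid] += acc_w;
            }
      }
    }
  }
  gin.attr("dim") = IntegerVector::create(nx, ny, nz, Ci, N);
  gw.attr("dim") = IntegerVector::create(k, k, k, Ci, Co);
  return List::create(_["gin"] = gin, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Average pooling, window = stride = m, ceil output dims, partial windows
// averaged over their actual voxel count.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".avgpool3d_fwd_cpp")]]
NumericVector avgpool3d_fwd_cpp(NumericVector input, IntegerVector idim, int m) {
  const int nx = idim[0], ny = idim[1], nz = idim[2], C = idim[3], N = idim[4];
  const int ox = (nx + m - 1) / m, oy = (ny + m - 1) / m, oz = (nz + m - 1) / m;
  const R_xlen_t ivs = (R_xlen_t)nx * ny * nz, ovs = (R_xlen_t)ox * oy * oz;
  NumericVector out(ovs * C * N);
  const double* in = input.begin();
  double* o = out.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* ip = in + cn * ivs;
    double* op = o + cn * ovs;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int x = 0; x < ox; ++x) {
          const int x1 = std::min(nx, (x + 1) * m), y1 = std::min(ny, (y + 1) * m),
                    z1 = std::min(nz, (z + 1) * m);
          double acc = 0.0; int cnt = 0;
          for (int zz = z * m; zz < z1; ++zz)
            for (int yy = y * m; yy < y1; ++yy)
              for (int xx = x * m; xx < x1; ++xx) {
                acc += ip[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
                ++cnt;
              }
          op[x + (R_xlen_t)ox * (y + (R_xlen_t)oy * z)] = acc / cnt;
        }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, C, N);
  return out;
}

// [[Rcpp::export(name = ".avgpool3d_bwd_cpp")]]
NumericVector avgpool3d_bwd_cpp(IntegerVector idim, NumericVector gout, int m) {
  const int nx = idim[0], ny = idim[1], nz = idim[2], C = idim[3], N = idim[4];
  const int ox = (nx + m - 1) / m, oy = (ny + m - 1) / m, oz = (nz + m - 1) / m;
  const R_xlen_t ivs = (R_xlen_t)nx * ny * nz, ovs = (R_xlen_t)ox * oy * oz;
  NumericVector gin(ivs * C * N);
  const double* go = gout.begin();
  double* gi = gin.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* gop = go + cn * ovs;
    double* gip = gi + cn * ivs;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int x = 0; x < ox; ++x) {
          const int x1 = std::min(nx, (x + 1) * m), y1 = std::min(ny, (y + 1) * m),
                    z1 = std::min(nz, (z + 1) * m);
          const int cnt = (x1 - x * m) * (y1 - y * m) * (z1 - z * m);
          const double g = gop[x + (R_xlen_t)ox * (y + (R_xlen_t)oy * z)] / cnt;
          for (int zz = z * m; zz < z1; ++zz)
            for (int yy = y * m; yy < y1; ++yy)
              for (int xx = x * m; xx < x1; ++xx)
                gip[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] += g;
        }
  }
  gin.attr("dim") = idim;
  return gin;
}

// ---------------------------------------------------------------------------
// Batch normalization over (spatial, batch) per channel. x is [S, C, N].
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".bn_fwd_cpp")]]
List bn_fwd_cpp(NumericVector x, R_xlen_t S, int C, int N,
                NumericVector gamma, NumericVector beta,
                NumericVector mean_in, NumericVector var_in,
                double eps, bool use_batch_stats) {
  NumericVector y(x.size());
  NumericVector mu(C), var(C);
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t tot = S * N;
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (use_batch_stats) {
      double acc = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* p = xp + ((R_xlen_t)n * C + c) * S;
        for (R_xlen_t i = 0; i < S; ++i) acc += p[i];
      }
      m = acc / tot;
      double acc2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* p = xp + ((R_xlen_t)n * C + c) * S;
        for (R_xlen_t i = 0; i < S; ++i) { double d = p[i] - m; acc2 += d * d; }
      }
      v = acc2 / tot;
    } else {
      m = mean_in[c]; v = var_in[c];
    }
    mu[c] = m; var[c] = v;
    const double sc = gamma[c] / std::sqrt(v + eps);
    const double sh = beta[c] - m * sc;
    for (int n = 0; n < N; ++n) {
      const double* p = xp + ((R_xlen_t)n * C + c) * S;
      double* q = yp + ((R_xlen_t)n * C + c) * S;
      for (R_xlen_t i = 0; i < S; ++i) q[i] = sc * p[i] + sh;
    }
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["mean"] = mu, _["var"] = var);
}

// [[Rcpp::export(name = ".bn_bwd_cpp")]]
List bn_bwd_cpp(NumericVector x, NumericVector gout, R_xlen_t S, int C, int N,
                NumericVector gamma, NumericVector mu, NumericVector var,
                double eps) {
  NumericVector gin(x.size()), ggamma(C), gbeta(C);
  const double* xp = x.begin();
  const double* gp = gout.begin();
  double* gi = gin.begin();
  const double tot = (double)S * N;
  for (int c = 0; c < C; ++c) {
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    double sum_g = 0.0, sum_gx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* px = xp + ((R_xlen_t)n * C + c) * S;
      const double* pg = gp + ((R_xlen_t)n * C + c) * S;
      for (R_xlen_t i = 0; i < S; ++i) {
        const double xh = (px[i] - mu[c]) * istd;
        sum_g += pg[i];
        sum_gx += pg[i] * xh;
      }
    }
    ggamma[c] = sum_gx;
    gbeta[c] = sum_g;
    const double k1 = gamma[c] * istd;
    for (int n = 0; n < N; ++n) {
      const double* px = xp + ((R_xlen_t)n * C + c) * S;
      const double* pg = gp + ((R_xlen_t)n * C + c) * S;
      double* pi = gi + ((R_xlen_t)n * C + c) * S;
      for (R_xlen_t i = 0; i < S; ++i) {
        const double xh = (px[i] - mu[c]) * istd;
        pi[i] = k1 * (pg[i] - sum_g / tot - xh * sum_gx / tot);
      }
    }
  }
  gin.attr("dim") = x.attr("dim");
  return List::create(_["gin"] = gin, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// ---------------------------------------------------------------------------
// Connected components on a boolean 3D volume; connectivity 6 or 26.
// Labels assigned in raster-scan discovery order, 1..ncomp.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t vs = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(vs);
  std::vector<R_xlen_t> stack;
  int next = 0;
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({dx, dy, dz});
      }
  for (R_xlen_t i = 0; i < vs; ++i) {
    if (!mask[i] || labels[i]) continue;
    ++next;
    labels[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((R_xlen_t)nx * ny);
      for (auto& d : nb) {
        int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[j] && !labels[j]) { labels[j] = next; stack.push_back(j); }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// ---------------------------------------------------------------------------
// Stage-1 probability smoothing: cubic-window mode filter on the winner-take-
// all label volume (ties -> lowest class index), then each voxel's probability
// vector is replaced by the mean over neighborhood voxels sharing the modal
// label. Voxels outside the mask are ignored and left untouched.
// probs is [nx,ny,nz,K]; labels 1..K inside mask, 0 outside.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mode_filter_cpp")]]
List mode_filter_cpp(NumericVector probs, IntegerVector labels,
                     LogicalVector mask, IntegerVector dim, int K, int window) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int r = (window - 1) / 2;
  const R_xlen_t vs = (R_xlen_t)nx * ny * nz;
  NumericVector out = clone(probs);
  IntegerVector lout = clone(labels);
  std::vector<int> counts(K + 1);
  std::vector<double> pacc(K);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (!mask[i]) continue;
        std::fill(counts.begin(), counts.end(), 0);
        for (int dz = -r; dz <= r; ++dz)
          for (int dy = -r; dy <= r; ++dy)
            for (int dx = -r; dx <= r; ++dx) {
              const int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                continue;
              const R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
              if (mask[j]) ++counts[labels[j]];
            }
        int best = 1;
        for (int c = 2; c <= K; ++c) if (counts[c] > counts[best]) best = c;
        lout[i] = best;
        // mean probability vector over neighbors carrying the modal label
        std::fill(pacc.begin(), pacc.end(), 0.0);
        int nn = 0;
        for (int dz = -r; dz <= r; ++dz)
          for (int dy = -r; dy <= r; ++dy)
            for (int dx = -r; dx <= r; ++dx) {
              const int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                continue;
              const R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
              if (mask[j] && labels[j] == best) {
                ++nn;
                for (int c = 0; c < K; ++c) pacc[c] += probs[j + vs * c];
              }
            }
        if (nn > 0)
          for (int c = 0; c < K; ++c) out[i + vs * c] = pacc[c] / nn;
      }
  return List::create(_["probs"] = out, _["labels"] = lout);
}
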