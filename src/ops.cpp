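// Low-level differentiable operators for multi-resolution SVF registration.
//
// Array conventions (match the R wrappers, column-major R memory):
//   feature map / vector field : dim c(C, n1, n2, n3), channel index fastest
//   scalar volume              : dim c(n1, n2, n3)
// All coordinates are 0-based voxel indices; out-of-range sampling is
// clamped to the border, and the sampling derivative w.r.t. a clamped
// coordinate is zero.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& C, int* n) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (C, n1, n2, n3)");
  C = d[0]; n[0] = d[1]; n[1] = d[2]; n[2] = d[3];
}

static inline void get_dims3(const NumericVector& x, int* n) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  n[0] = d[0]; n[1] = d[1]; n[2] = d[2];
}

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

// ---------------------------------------------------------------- avgpool ---

// Kernel-3, stride-2 average pooling with 1-voxel replicate padding, so each
// output dimension is ceil(n/2) (exactly n/2 for even n).
// [[Rcpp::export]]
NumericVector cpp_avgpool3(NumericVector x) {
  int n[3]; get_dims3(x, n);
  int o[3];
  for (int a = 0; a < 3; ++a) o[a] = (n[a] - 1) / 2 + 1;
  NumericVector y(o[0] * (R_xlen_t)o[1] * o[2]);
  y.attr("dim") = IntegerVector::create(o[0], o[1], o[2]);
  const double* px = x.begin();
  double* py = y.begin();
  for (int k = 0; k < o[2]; ++k)
    for (int j = 0; j < o[1]; ++j)
      for (int i = 0; i < o[0]; ++i) {
        double s = 0.0;
        for (int dk = -1; dk <= 1; ++dk) {
          int kk = clampi(2 * k + dk, 0, n[2] - 1);
          for (int dj = -1; dj <= 1; ++dj) {
            int jj = clampi(2 * j + dj, 0, n[1] - 1);
            for (int di = -1; di <= 1; ++di) {
              int ii = clampi(2 * i + di, 0, n[0] - 1);
              s += px[ii + (R_xlen_t)n[0] * (jj + (R_xlen_t)n[1] * kk)];
            }
          }
        }
        py[i + (R_xlen_t)o[0] * (j + (R_xlen_t)o[1] * k)] = s / 27.0;
      }
  return y;
}

// ------------------------------------------------------- trilinear sampling --

// y[c](p) = x[c](clamp(p + u(p))); x is (C, n), u is (3, n) on the same grid.
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector x, NumericVector disp) {
  int C, n[3]; get_dims4(x, C, n);
  int Cd, nd[3]; get_dims4(disp, Cd, nd);
  if (Cd != 3 || nd[0] != n[0] || nd[1] != n[1] || nd[2] != n[2])
    stop("displacement must be (3, n1, n2, n3) matching the image grid");
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* px = x.begin();
  const double* pu = disp.begin();
  double* py = y.begin();
  const R_xlen_t sx1 = C, sx2 = (R_xlen_t)C * n[0], sx3 = (R_xlen_t)C * n[0] * n[1];
  for (int k = 0; k < n[2]; ++k)
    for (int j = 0; j < n[1]; ++j)
      for (int i = 0; i < n[0]; ++i) {
        R_xlen_t vox = i + (R_xlen_t)n[0] * (j + (R_xlen_t)n[1] * k);
        double q0 = i + pu[3 * vox + 0];
        double q1 = j + pu[3 * vox + 1];
        double q2 = k + pu[3 * vox + 2];
        q0 = q0 < 0 ? 0 : (q0 > n[0] - 1 ? n[0] - 1 : q0);
        q1 = q1 < 0 ? 0 : (q1 > n[1] - 1 ? n[1] - 1 : q1);
        q2 = q2 < 0 ? 0 : (q2 > n[2] - 1 ? n[2] - 1 : q2);
        int i0 = n[0] > 1 ? std::min((int)q0, n[0] - 2) : 0;
        int j0 = n[1] > 1 ? std::min((int)q1, n[1] - 2) : 0;
        int k0 = n[2] > 1 ? std::min((int)q2, n[2] - 2) : 0;
        double a = q0 - i0, b = q1 - j0, c = q2 - k0;
        R_xlen_t d1 = n[0] > 1 ? sx1 : 0, d2 = n[1] > 1 ? sx2 : 0,
                 d3 = n[2] > 1 ? sx3 : 0;
        const double* p = px + sx1 * i0 + sx2 * j0 + sx3 * k0;
        double w000 = (1-a)*(1-b)*(1-c), w100 = a*(1-b)*(1-c);
        double w010 = (1-a)*b*(1-c),     w110 = a*b*(1-c);
        double w001 = (1-a)*(1-b)*c,     w101 = a*(1-b)*c;
        double w011 = (1-a)*b*c,         w111 = a*b*c;
        double* q = py + C * vox;
        for (int ch = 0; ch < C; ++ch) {
          q[ch] = w000*p[ch] + w100*p[ch+d1] + w010*p[ch+d2] + w110*p[ch+d1+d2]
                + w001*p[ch+d3] + w101*p[ch+d1+d3] + w011*p[ch+d2+d3]
                + w111*p[ch+d1+d2+d3];
        }
      }
  return y;
}

// Backward pass of cpp_sample_trilinear: returns gradients w.r.t. the image
// (scatter of the interpolation weights) and w.r.t. the displacement (image
// spatial derivative at the sample point; zero along clamped axes).
// [[Rcpp::export]]
List cpp_sample_trilinear_bw(NumericVector x, NumericVector disp,
                             NumericVector gy) {
  int C, n[3]; get_dims4(x, C, n);
  NumericVector gx(x.size()), gu(disp.size());
  gx.attr("dim") = x.attr("dim");
  gu.attr("dim") = disp.attr("dim");
  const double* px = x.begin();
  const double* pu = disp.begin();
  const double* pg = gy.begin();
  double* pgx = gx.begin();
  double* pgu = gu.begin();
  const R_xlen_t sx1 = C, sx2 = (R_xlen_t)C * n[0], sx3 = (R_xlen_t)C * n[0] * n[1];
  for (int k = 0; k < n[2]; ++k)
    for (int j = 0; j < n[1]; ++j)
      for (int i = 0; i < n[0]; ++i) {
        R_xlen_t vox = i + (R_xlen_t)n[0] * (j + (R_xlen_t)n[1] * k);
        double q0 = i + pu[3 * vox + 0];
        double q1 = j + pu[3 * vox + 1];
        double q2 = k + pu[3 * vox + 2];
        double in0 = (q0 > 0 && q0 < n[0] - 1) ? 1.0 : 0.0;
        double in1 = (q1 > 0 && q1 < n[1] - 1) ? 1.0 : 0.0;
        double in2 = (q2 > 0 && q2 < n[2] - 1) ? 1.0 : 0.0;
        q0 = q0 < 0 ? 0 : (q0 > n[0] - 1 ? n[0] - 1 : q0);
        q1 = q1 < 0 ? 0 : (q1 > n[1] - 1 ? n[1] - 1 : q1);
        q2 = q2 < 0 ? 0 : (q2 > n[2] - 1 ? n[2] - 1 : q2);
        int i0 = n[0] > 1 ? std::min((int)q0, n[0] - 2) : 0;
        int j0 = n[1] > 1 ? std::min((int)q1, n[1] - 2) : 0;
        int k0 = n[2] > 1 ? std::min((int)q2, n[2] - 2) : 0;
        double a = q0 - i0, b = q1 - j0, c = q2 - k0;
        R_xlen_t d1 = n[0] > 1 ? sx1 : 0, d2 = n[1] > 1 ? sx2 : 0,
                 d3 = n[2] > 1 ? sx3 : 0;
        R_xlen_t base = sx1 * i0 + sx2 * j0 + sx3 * k0;
        const double* p = px + base;
        double* gp = pgx + base;
        double w000 = (1-a)*(1-b)*(1-c), w100 = a*(1-b)*(1-c);
        double w010 = (1-a)*b*(1-c),     w110 = a*b*(1-c);
        double w001 = (1-a)*(1-b)*c,     w101 = a*(1-b)*c;
        double w011 = (1-a)*b*c,         w111 = a*b*c;
        double g0 = 0, g1 = 0, g2 = 0;
        for (int ch = 0; ch < C; ++ch) {
          double g = pg[ch + C * vox];
          double v000 = p[ch],       v100 = p[ch+d1];
          double v010 = p[ch+d2],    v110 = p[ch+d1+d2];
          double v001 = p[ch+d3],    v101 = p[ch+d1+d3];
          double v011 = p[ch+d2+d3], v111 = p[ch+d1+d2+d3];
          gp[ch] += g * w000;        gp[ch+d1] += g * w100;
          gp[ch+d2] += g * w010;     gp[ch+d1+d2] += g * w110;
          gp[ch+d3] += g * w001;     gp[ch+d1+d3] += g * w101;
          gp[ch+d2+d3] += g * w011;  gp[ch+d1+d2+d3] += g * w111;
          g0 += g * ((1-b)*(1-c)*(v100 - v000) + b*(1-c)*(v110 - v010)
                   + (1-b)*c*(v101 - v001)     + b*c*(v111 - v011));
          g1 += g * ((1-a)*(1-c)*(v010 - v000) + a*(1-c)*(v110 - v100)
                   + (1-a)*c*(v011 - v001)     + a*c*(v111 - v101));
          g2 += g * ((1-a)*(1-b)*(v001 - v000) + a*(1-b)*(v101 - v100)
                   + (1-a)*b*(v011 - v010)     + a*b*(v111 - v110));
        }
        pgu[3 * vox + 0] = g0 * in0;
        pgu[3 * vox + 1] = g1 * in1;
        pgu[3 * vox + 2] = g2 * in2;
      }
  return List::create(_["gx"] = gx, _["gdisp"] = gu);
}

// Nearest-neighbour variant for label maps (not differentiable).
// [[Rcpp::export]]
NumericVector cpp_sample_nearest(NumericVector x, NumericVector disp) {
  int C, n[3]; get_dims4(x, C, n);
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* px = x.begin();
  const double* pu = disp.begin();
  double* py = y.begin();
  const R_xlen_t sx1 = C, sx2 = (R_xlen_t)C * n[0], sx3 = (R_xlen_t)C * n[0] * n[1];
  for (int k = 0; k < n[2]; ++k)
    for (int j = 0; j < n[1]; ++j)
      for (int i = 0; i < n[0]; ++i) {
        R_xlen_t vox = i + (R_xlen_t)n[0] * (j + (R_xlen_t)n[1] * k);
        int ii = clampi((int)std::lround(i + pu[3 * vox + 0]), 0, n[0] - 1);
        int jj = clampi((int)std::lround(j + pu[3 * vox + 1]), 0, n[1] - 1);
        int kk = clampi((int)std::lround(k + pu[3 * vox + 2]), 0, n[2] - 1);
        for (int ch = 0; ch < C; ++ch)
          py[ch + C * vox] = px[ch + sx1 * ii + sx2 * jj + sx3 * kk];
      }
  return y;
}

// ------------------------------------------------------------ resize (up) ---

struct AxisMap { std::vector<int> i0; std::vector<double> w; };

static AxisMap axis_map(int n_in, int n_out) {
  AxisMap m; m.i0.resize(n_out); m.w.resize(n_out);
  for (int t = 0; t < n_out; ++t) {
    double s = (n_out == 1 || n_in == 1)
      ? 0.0 : (double)t * (n_in - 1) / (n_out - 1);
    int i0 = n_in > 1 ? std::min((int)s, n_in - 2) : 0;
    m.i0[t] = i0; m.w[t] = s - i0;
  }
  return m;
}

// Channel-wise trilinear resize onto a (usually finer) grid; grid nodes are
// aligned at the corners, so coincident nodes reproduce source values exactly.
// [[Rcpp::export]]
NumericVector cpp_resize_trilinear(NumericVector x, IntegerVector out_dim) {
  int C, n[3]; get_dims4(x, C, n);
  int o[3] = { out_dim[0], out_dim[1], out_dim[2] };
  AxisMap m0 = axis_map(n[0], o[0]), m1 = axis_map(n[1], o[1]),
          m2 = axis_map(n[2], o[2]);
  NumericVector y((R_xlen_t)C * o[0] * o[1] * o[2]);
  y.attr("dim") = IntegerVector::create(C, o[0], o[1], o[2]);
  const double* px = x.begin();
  double* py = y.begin();
  const R_xlen_t sx1 = C, sx2 = (R_xlen_t)C * n[0], sx3 = (R_xlen_t)C * n[0] * n[1];
  for (int k = 0; k < o[2]; ++k) {
    int k0 = m2.i0[k], k1 = std::min(k0 + 1, n[2] - 1); double c = m2.w[k];
    for (int j = 0; j < o[1]; ++j) {
      int j0 = m1.i0[j], j1 = std::min(j0 + 1, n[1] - 1); double b = m1.w[j];
      for (int i = 0; i < o[0]; ++i) {
        int i0 = m0.i0[i], i1 = std::min(i0 + 1, n[0] - 1); double a = m0.w[i];
        R_xlen_t vox = i + (R_xlen_t)o[0] * (j + (R_xlen_t)o[1] * k);
        for (int ch = 0; ch < C; ++ch) {
          #define XAT(ii,jj,kk) px[ch + sx1*(ii) + sx2*(jj) + sx3*(kk)]
          py[ch + C * vox] =
              (1-a)*(1-b)*(1-c)*XAT(i0,j0,k0) + a*(1-b)*(1-c)*XAT(i1,j0,k0)
            + (1-a)*b*(1-c)*XAT(i0,j1,k0)     + a*b*(1-c)*XAT(i1,j1,k0)
            + (1-a)*(1-b)*c*XAT(i0,j0,k1)     + a*(1-b)*c*XAT(i1,j0,k1)
            + (1-a)*b*c*XAT(i0,j1,k1)         + a*b*c*XAT(i1,j1,k1);
          #undef XAT
        }
      }
    }
  }
  return y;
}

// Adjoint of cpp_resize_trilinear (scatter-add of the same weights).
// [[Rcpp::export]]
NumericVector cpp_resize_trilinear_bw(NumericVector gy, IntegerVector in_dim) {
  int C, o[3]; get_dims4(gy, C, o);
  int n[3] = { in_dim[0], in_dim[1], in_dim[2] };
  AxisMap m0 = axis_map(n[0], o[0]), m1 = axis_map(n[1], o[1]),
          m2 = axis_map(n[2], o[2]);
  NumericVector gx((R_xlen_t)C * n[0] * n[1] * n[2]);
  gx.attr("dim") = IntegerVector::create(C, n[0], n[1], n[2]);
  const double* pg = gy.begin();
  double* px = gx.begin();
  const R_xlen_t sx1 = C, sx2 = (R_xlen_t)C * n[0], sx3 = (R_xlen_t)C * n[0] * n[1];
  for (int k = 0; k < o[2]; ++k) {
    int k0 = m2.i0[k], k1 = std::min(k0 + 1, n[2] - 1); double c = m2.w[k];
    for (int j = 0; j < o[1]; ++j) {
      int j0 = m1.i0[j], j1 = std::min(j0 + 1, n[1] - 1); double b = m1.w[j];
      for (int i = 0; i < o[0]; ++i) {
        int i0 = m0.i0[i], i1 = std::min(i0 + 1, n[0] - 1); double a = m0.w[i];
        R_xlen_t vox = i + (R_xlen_t)o[0] * (j + (R_xlen_t)o[1] * k);
        for (int ch = 0; ch < C; ++ch) {
          double g = pg[ch + C * vox];
          if (g == 0.0) continue;
          #define GXAT(ii,jj,kk) px[ch + sx1*(ii) + sx2*(jj) + sx3*(kk)]
          GXAT(i0,j0,k0) += g * (1-a)*(1-b)*(1-c);
          GXAT(i1,j0,k0) += g * a*(1-b)*(1-c);
          GXAT(i0,j1,k0) += g * (1-a)*b*(1-c);
          GXAT(i1,j1,k0) += g * a*b*(1-c);
          GXAT(i0,j0,k1) += g * (1-a)*(1-b)*c;
          GXAT(i1,j0,k1) += g * a*(1-b)*c;
          GXAT(i0,j1,k1) += g * (1-a)*b*c;
          GXAT(i1,j1,k1) += g * a*b*c;
          #undef GXAT
        }
      }
    }
  }
  return gx;
}

// ------------------------------------------------- separable convolution ----

// One separable pass along each spatial axis with a shared 1-D kernel and
// replicate borders; adjoint = scatter with the same clamped indices.
static void sep_pass(const double* x, double* y, int C, const int* n,
                     const std::vector<double>& ker, int axis, bool adjoint) {
  int K = (int)ker.size(), r = (K - 1) / 2;
  R_xlen_t stride[3] = { C, (R_xlen_t)C * n[0], (R_xlen_t)C * n[0] * n[1] };
  for (int k = 0; k < n[2]; ++k)
    for (int j = 0; j < n[1]; ++j)
      for (int i = 0; i < n[0]; ++i) {
        int idx3[3] = { i, j, k };
        R_xlen_t vox = i + (R_xlen_t)n[0] * (j + (R_xlen_t)n[1] * k);
        for (int t = 0; t < K; ++t) {
          int src = clampi(idx3[axis] + t - r, 0, n[axis] - 1);
          R_xlen_t off = (R_xlen_t)(src - idx3[axis]) * stride[axis];
          for (int ch = 0; ch < C; ++ch) {
            if (!adjoint)
              y[ch + C * vox] += ker[t] * x[ch + C * vox + off];
            else
              y[ch + C * vox + off] += ker[t] * x[ch + C * vox];
          }
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_sepconv3(NumericVector x, NumericVector kernel, bool adjoint) {
  int C, n[3]; get_dims4(x, C, n);
  std::vector<double> ker(kernel.begin(), kernel.end());
  NumericVector cur = clone(x);
  for (int axis = 0; axis < 3; ++axis) {
    NumericVector nxt(x.size());
    nxt.attr("dim") = x.attr("dim");
    sep_pass(cur.begin(), nxt.begin(), C, n, ker, axis, adjoint);
    cur = nxt;
  }
  return cur;
}

// ------------------------------------------------------------ convolution ---

static void out_dims(const int* n, int K, int s, int p, int* o) {
  for (int a = 0; a < 3; ++a) o[a] = (n[a] + 2 * p - K) / s + 1;
}

static arma::mat im2col(const double* x, int Ci, const int* n, int K, int s,
                        int p, const int* o) {
  R_xlen_t O = (R_xlen_t)o[0] * o[1] * o[2];
  arma::mat col((R_xlen_t)Ci * K * K * K, O, arma::fill::zeros);
  const R_xlen_t sx1 = Ci, sx2 = (R_xlen_t)Ci * n[0], sx3 = (R_xlen_t)Ci * n[0] * n[1];
  R_xlen_t ocol = 0;
  for (int k = 0; k < o[2]; ++k)
    for (int j = 0; j < o[1]; ++j)
      for (int i = 0; i < o[0]; ++i, ++ocol) {
        double* dst = col.colptr(ocol);
        for (int kz = 0; kz < K; ++kz) {
          int zz = k * s - p + kz;
          if (zz < 0 || zz >= n[2]) continue;
          for (int ky = 0; ky < K; ++ky) {
            int yy = j * s - p + ky;
            if (yy < 0 || yy >= n[1]) continue;
            for (int kx = 0; kx < K; ++kx) {
              int xx = i * s - p + kx;
              if (xx < 0 || xx >= n[0]) continue;
              std::memcpy(dst + (R_xlen_t)Ci * (kx + K * (ky + K * kz)),
                          x + sx1 * xx + sx2 * yy + sx3 * zz,
                          sizeof(double) * Ci);
            }
          }
        }
      }
  return col;
}

static void col2im_add(const arma::mat& col, double* gx, int Ci, const int* n,
                       int K, int s, int p, const int* o) {
  const R_xlen_t sx1 = Ci, sx2 = (R_xlen_t)Ci * n[0], sx3 = (R_xlen_t)Ci * n[0] * n[1];
  R_xlen_t ocol = 0;
  for (int k = 0; k < o[2]; ++k)
    for (int j = 0; j < o[1]; ++j)
      for (int i = 0; i < o[0]; ++i, ++ocol) {
        const double* src0 = col.colptr(ocol);
        for (int kz = 0; kz < K; ++kz) {
          int zz = k * s - p + kz;
          if (zz < 0 || zz >= n[2]) continue;
          for (int ky = 0; ky < K; ++ky) {
            int yy = j * s - p + ky;
            if (yy < 0 || yy >= n[1]) continue;
            for (int kx = 0; kx < K; ++kx) {
              int xx = i * s - p + kx;
              if (xx < 0 || xx >= n[0]) continue;
              double* dst = gx + sx1 * xx + sx2 * yy + sx3 * zz;
              const double* src = src0 + (R_xlen_t)Ci * (kx + K * (ky + K * kz));
              for (int c = 0; c < Ci; ++c) dst[c] += src[c];
            }
          }
        }
      }
}

// ---- tap-wise GEMM fast path for stride-1, pad-1, kernel-3 convolutions ----
//
// The input is copied once into a zero-haloed flat matrix; each of the 27
// kernel taps is then a single GEMM against a column-shifted view, so no
// im2col matrix (27x the input) is ever materialized.

struct FlatPad {
  arma::mat m;       // (C, P + 2*maxoff), zero outside the interior payload
  int pn[3];         // padded dims
  R_xlen_t P, maxoff;
};

static FlatPad flat_pad(const double* x, int C, const int* n) {
  FlatPad f;
  for (int a = 0; a < 3; ++a) f.pn[a] = n[a] + 2;
  f.P = (R_xlen_t)f.pn[0] * f.pn[1] * f.pn[2];
  f.maxoff = 1 + f.pn[0] + (R_xlen_t)f.pn[0] * f.pn[1];
  f.m.zeros(C, f.P + 2 * f.maxoff);
  for (int k = 0; k < n[2]; ++k)
    for (int j = 0; j < n[1]; ++j) {
      R_xlen_t src = (R_xlen_t)C * n[0] * (j + (R_xlen_t)n[1] * k);
      R_xlen_t pcol = 1 + (R_xlen_t)f.pn[0] * ((j + 1) + (R_xlen_t)f.pn[1] * (k + 1));
      std::memcpy(f.m.colptr(f.maxoff + pcol), x + src,
                  sizeof(double) * C * n[0]);
    }
  return f;
}

static void flat_unpad(const arma::mat& Y, double* y, int C, const int* n,
                       const int* pn, R_xlen_t shift) {
  for (int k = 0; k < n[2]; ++k)
    for (int j = 0; j < n[1]; ++j) {
      R_xlen_t dst = (R_xlen_t)C * n[0] * (j + (R_xlen_t)n[1] * k);
      R_xlen_t pcol = 1 + (R_xlen_t)pn[0] * ((j + 1) + (R_xlen_t)pn[1] * (k + 1));
      std::memcpy(y + dst, Y.colptr(shift + pcol), sizeof(double) * C * n[0]);
    }
}

static inline R_xlen_t tap_off(int kx, int ky, int kz, const int* pn) {
  return (kx - 1) + (R_xlen_t)pn[0] * (ky - 1) +
         (R_xlen_t)pn[0] * pn[1] * (kz - 1);
}

static void conv3d_s1_fw(const double* x, const double* w, const double* b,
                         int Ci, int Co, const int* n, double* y) {
  FlatPad f = flat_pad(x, Ci, n);
  arma::mat Y(Co, f.P, arma::fill::zeros);
  for (int kz = 0; kz < 3; ++kz)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        arma::mat Wk(const_cast<double*>(
            w + (R_xlen_t)Co * Ci * (kx + 3 * (ky + 3 * kz))), Co, Ci,
            false, true);
        R_xlen_t off = f.maxoff + tap_off(kx, ky, kz, f.pn);
        Y += Wk * f.m.cols(off, off + f.P - 1);
      }
  flat_unpad(Y, y, Co, n, f.pn, 0);
  R_xlen_t N = (R_xlen_t)n[0] * n[1] * n[2];
  for (R_xlen_t t = 0; t < N; ++t)
    for (int c = 0; c < Co; ++c) y[c + (R_xlen_t)Co * t] += b[c];
}

static void conv3d_s1_bw(const double* x, const double* w, const double* gy,
                         int Ci, int Co, const int* n,
                         double* gx, double* gw, double* gb) {
  FlatPad fx = flat_pad(x, Ci, n);
  FlatPad fg = flat_pad(gy, Co, n);
  arma::mat GX(Ci, fx.P, arma::fill::zeros);
  arma::mat Gint = fg.m.cols(fg.maxoff, fg.maxoff + fg.P - 1);
  for (int kz = 0; kz < 3; ++kz)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        R_xlen_t widx = (R_xlen_t)Co * Ci * (kx + 3 * (ky + 3 * kz));
        arma::mat Wk(const_cast<double*>(w + widx), Co, Ci, false, true);
        R_xlen_t off = tap_off(kx, ky, kz, fx.pn);
        // d x: scatter of W^T g at the opposite offset
        GX += Wk.t() * fg.m.cols(fg.maxoff - off, fg.maxoff - off + fg.P - 1);
        // d W_k = g (interior) x_shifted^T
        arma::mat gWk = Gint *
          fx.m.cols(fx.maxoff + off, fx.maxoff + off + fx.P - 1).t();
        std::memcpy(gw + widx, gWk.memptr(), sizeof(double) * Co * Ci);
      }
  flat_unpad(GX, gx, Ci, n, fx.pn, 0);
  R_xlen_t N = (R_xlen_t)n[0] * n[1] * n[2];
  for (R_xlen_t t = 0; t < N; ++t)
    for (int c = 0; c < Co; ++c) gb[c] += gy[c + (R_xlen_t)Co * t];
}

// Strided 3-D convolution, weight layout (Co, Ci, K, K, K).
// [[Rcpp::export]]
NumericVector cpp_conv3d(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  int Ci, n[3]; get_dims4(x, Ci, n);
  IntegerVector wd = w.attr("dim");
  int Co = wd[0], K = wd[2];
  if (wd[1] != Ci) stop("weight input channels mismatch");
  if (stride == 1 && pad == 1 && K == 3) {
    NumericVector y((R_xlen_t)Co * n[0] * n[1] * n[2]);
    y.attr("dim") = IntegerVector::create(Co, n[0], n[1], n[2]);
    conv3d_s1_fw(x.begin(), w.begin(), b.begin(), Ci, Co, n, y.begin());
    return y;
  }
  int o[3]; out_dims(n, K, stride, pad, o);
  arma::mat col = im2col(x.begin(), Ci, n, K, stride, pad, o);
  arma::mat Wm(const_cast<double*>(w.begin()), Co, (R_xlen_t)Ci * K * K * K,
               false, true);
  arma::mat ym = Wm * col;
  NumericVector y(ym.n_elem);
  y.attr("dim") = IntegerVector::create(Co, o[0], o[1], o[2]);
  double* py = y.begin();
  std::memcpy(py, ym.memptr(), sizeof(double) * ym.n_elem);
  R_xlen_t O = (R_xlen_t)o[0] * o[1] * o[2];
  for (R_xlen_t t = 0; t < O; ++t)
    for (int c = 0; c < Co; ++c) py[c + (R_xlen_t)Co * t] += b[c];
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  int Ci, n[3]; get_dims4(x, Ci, n);
  IntegerVector wd = w.attr("dim");
  int Co = wd[0], K = wd[2];
  if (stride == 1 && pad == 1 && K == 3) {
    NumericVector gx(x.size()), gwv(w.size()), gb(Co);
    gx.attr("dim") = x.attr("dim");
    gwv.attr("dim") = w.attr("dim");
    conv3d_s1_bw(x.begin(), w.begin(), gy.begin(), Ci, Co, n,
                 gx.begin(), gwv.begin(), gb.begin());
    return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gb);
  }
  int o[3]; get_dims4(gy, Co, o);
  R_xlen_t O = (R_xlen_t)o[0] * o[1] * o[2];
  arma::mat col = im2col(x.begin(), Ci, n, K, stride, pad, o);
  arma::mat Wm(const_cast<double*>(w.begin()), Co, (R_xlen_t)Ci * K * K * K,
               false, true);
  arma::mat gym(const_cast<double*>(gy.begin()), Co, O, false, true);
  arma::mat gW = gym * col.t();
  arma::vec gb = arma::sum(gym, 1);
  arma::mat gcol = Wm.t() * gym;
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  col2im_add(gcol, gx.begin(), Ci, n, K, stride, pad, o);
  NumericVector gwv(gW.n_elem);
  gwv.attr("dim") = w.attr("dim");
  std::memcpy(gwv.begin(), gW.memptr(), sizeof(double) * gW.n_elem);
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Transposed convolution, kernel 3, stride 2, padding 1, output padding 1:
// each output dimension is exactly twice the input dimension. Weight layout
// (Ci, Co, 3, 3, 3) — the orientation of the conv this op is the adjoint of.
// [[Rcpp::export]]
NumericVector cpp_convt3d(NumericVector x, NumericVector w, NumericVector b) {
  int Ci, n[3]; get_dims4(x, Ci, n);
  IntegerVector wd = w.attr("dim");
  if (wd[0] != Ci) stop("weight input channels mismatch");
  int Co = wd[1], K = wd[2];
  int onn[3] = { 2 * n[0], 2 * n[1], 2 * n[2] };
  R_xlen_t N = (R_xlen_t)n[0] * n[1] * n[2];
  arma::mat Wm(const_cast<double*>(w.begin()), Ci, (R_xlen_t)Co * K * K * K,
               false, true);
  arma::mat xm(const_cast<double*>(x.begin()), Ci, N, false, true);
  arma::mat gcol = Wm.t() * xm;
  NumericVector y((R_xlen_t)Co * onn[0] * onn[1] * onn[2]);
  y.attr("dim") = IntegerVector::create(Co, onn[0], onn[1], onn[2]);
  col2im_add(gcol, y.begin(), Co, onn, K, 2, 1, n);
  double* py = y.begin();
  R_xlen_t O = (R_xlen_t)onn[0] * onn[1] * onn[2];
  for (R_xlen_t t = 0; t < O; ++t)
    for (int c = 0; c < Co; ++c) py[c + (R_xlen_t)Co * t] += b[c];
  return y;
}

// [[Rcpp::export]]
List cpp_convt3d_bw(NumericVector x, NumericVector w, NumericVector gy) {
  int Ci, n[3]; get_dims4(x, Ci, n);
  IntegerVector wd = w.attr("dim");
  int Co = wd[1], K = wd[2];
  int onn[3]; int Cog; get_dims4(gy, Cog, onn);
  R_xlen_t N = (R_xlen_t)n[0] * n[1] * n[2];
  R_xlen_t O = (R_xlen_t)onn[0] * onn[1] * onn[2];
  arma::mat Wm(const_cast<double*>(w.begin()), Ci, (R_xlen_t)Co * K * K * K,
               false, true);
  arma::mat col_g = im2col(gy.begin(), Co, onn, K, 2, 1, n);
  arma::mat gxm = Wm * col_g;
  arma::mat xm(const_cast<double*>(x.begin()), Ci, N, false, true);
  arma::mat gW = xm * col_g.t();
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  std::memcpy(gx.begin(), gxm.memptr(), sizeof(double) * gxm.n_elem);
  NumericVector gwv(gW.n_elem);
  gwv.attr("dim") = w.attr("dim");
  std::memcpy(gwv.begin(), gW.memptr(), sizeof(double) * gW.n_elem);
  NumericVector gb(Co);
  const double* pg = gy.begin();
  for (R_xlen_t t = 0; t < O; ++t)
    for (int c = 0; c < Co; ++c) gb[c] += pg[c + (R_xlen_t)Co * t];
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gb);
}

// ------------------------------------------- fused scaling-and-squaring -----

// One self-composition r(x) = u(x) + u(x + u(x)) fused in C++.
static void compose_self(const double* pu, double* pr, const int* n) {
  const R_xlen_t s1 = 3, s2 = (R_xlen_t)3 * n[0], s3 = (R_xlen_t)3 * n[0] * n[1];
  for (int k = 0; k < n[2]; ++k)
    for (int j = 0; j < n[1]; ++j)
      for (int i = 0; i < n[0]; ++i) {
        R_xlen_t vox = i + (R_xlen_t)n[0] * (j + (R_xlen_t)n[1] * k);
        double q0 = i + pu[3 * vox + 0];
        double q1 = j + pu[3 * vox + 1];
        double q2 = k + pu[3 * vox + 2];
        q0 = q0 < 0 ? 0 : (q0 > n[0] - 1 ? n[0] - 1 : q0);
        q1 = q1 < 0 ? 0 : (q1 > n[1] - 1 ? n[1] - 1 : q1);
        q2 = q2 < 0 ? 0 : (q2 > n[2] - 1 ? n[2] - 1 : q2);
        int i0 = n[0] > 1 ? std::min((int)q0, n[0] - 2) : 0;
        int j0 = n[1] > 1 ? std::min((int)q1, n[1] - 2) : 0;
        int k0 = n[2] > 1 ? std::min((int)q2, n[2] - 2) : 0;
        double a = q0 - i0, b = q1 - j0, c = q2 - k0;
        R_xlen_t d1 = n[0] > 1 ? s1 : 0, d2 = n[1] > 1 ? s2 : 0,
                 d3 = n[2] > 1 ? s3 : 0;
        const double* p = pu + s1 * i0 + s2 * j0 + s3 * k0;
        double w000 = (1-a)*(1-b)*(1-c), w100 = a*(1-b)*(1-c);
        double w010 = (1-a)*b*(1-c),     w110 = a*b*(1-c);
        double w001 = (1-a)*(1-b)*c,     w101 = a*(1-b)*c;
        double w011 = (1-a)*b*c,         w111 = a*b*c;
        for (int ch = 0; ch < 3; ++ch)
          pr[ch + 3 * vox] = pu[ch + 3 * vox]
            + w000*p[ch] + w100*p[ch+d1] + w010*p[ch+d2] + w110*p[ch+d1+d2]
            + w001*p[ch+d3] + w101*p[ch+d1+d3] + w011*p[ch+d2+d3]
            + w111*p[ch+d1+d2+d3];
      }
}

// Scaling-and-squaring integration with per-step caches for backprop.
// [[Rcpp::export]]
List cpp_integrate(NumericVector v, int steps) {
  int C, n[3]; get_dims4(v, C, n);
  if (C != 3) stop("velocity field must have 3 channels");
  List cache(steps);
  NumericVector u = clone(v);
  double sc = std::pow(2.0, -steps);
  for (R_xlen_t t = 0; t < u.size(); ++t) u[t] *= sc;
  for (int s = 0; s < steps; ++s) {
    cache[s] = u;
    NumericVector r(u.size());
    r.attr("dim") = v.attr("dim");
    compose_self(u.begin(), r.begin(), n);
    u = r;
  }
  return List::create(_["u"] = u, _["cache"] = cache, _["steps"] = steps);
}

// Backward of one self-composition, fused: given g = dL/dr, returns
// dL/du = g + J-term + scatter-term in a single pass.
static void compose_self_bw(const double* pu, const double* pg, double* pgu,
                            const int* n) {
  const R_xlen_t s1 = 3, s2 = (R_xlen_t)3 * n[0], s3 = (R_xlen_t)3 * n[0] * n[1];
  R_xlen_t total = (R_xlen_t)3 * n[0] * n[1] * n[2];
  std::memcpy(pgu, pg, sizeof(double) * total); // ginner identity part
  for (int k = 0; k < n[2]; ++k)
    for (int j = 0; j < n[1]; ++j)
      for (int i = 0; i < n[0]; ++i) {
        R_xlen_t vox = i + (R_xlen_t)n[0] * (j + (R_xlen_t)n[1] * k);
        double q0 = i + pu[3 * vox + 0];
        double q1 = j + pu[3 * vox + 1];
        double q2 = k + pu[3 * vox + 2];
        double in0 = (q0 > 0 && q0 < n[0] - 1) ? 1.0 : 0.0;
        double in1 = (q1 > 0 && q1 < n[1] - 1) ? 1.0 : 0.0;
        double in2 = (q2 > 0 && q2 < n[2] - 1) ? 1.0 : 0.0;
        q0 = q0 < 0 ? 0 : (q0 > n[0] - 1 ? n[0] - 1 : q0);
        q1 = q1 < 0 ? 0 : (q1 > n[1] - 1 ? n[1] - 1 : q1);
        q2 = q2 < 0 ? 0 : (q2 > n[2] - 1 ? n[2] - 1 : q2);
        int i0 = n[0] > 1 ? std::min((int)q0, n[0] - 2) : 0;
        int j0 = n[1] > 1 ? std::min((int)q1, n[1] - 2) : 0;
        int k0 = n[2] > 1 ? std::min((int)q2, n[2] - 2) : 0;
        double a = q0 - i0, b = q1 - j0, c = q2 - k0;
        R_xlen_t d1 = n[0] > 1 ? s1 : 0, d2 = n[1] > 1 ? s2 : 0,
                 d3 = n[2] > 1 ? s3 : 0;
        R_xlen_t base = s1 * i0 + s2 * j0 + s3 * k0;
        const double* p = pu + base;
        double* gp = pgu + base;
        double w000 = (1-a)*(1-b)*(1-c), w100 = a*(1-b)*(1-c);
        double w010 = (1-a)*b*(1-c),     w110 = a*b*(1-c);
        double w001 = (1-a)*(1-b)*c,     w101 = a*(1-b)*c;
        double w011 = (1-a)*b*c,         w111 = a*b*c;
        double g0 = 0, g1 = 0, g2 = 0;
        for (int ch = 0; ch < 3; ++ch) {
          double g = pg[ch + 3 * vox];
          double v000 = p[ch],       v100 = p[ch+d1];
          double v010 = p[ch+d2],    v110 = p[ch+d1+d2];
          double v001 = p[ch+d3],    v101 = p[ch+d1+d3];
          double v011 = p[ch+d2+d3], v111 = p[ch+d1+d2+d3];
          gp[ch] += g * w000;        gp[ch+d1] += g * w100;
          gp[ch+d2] += g * w010;     gp[ch+d1+d2] += g * w110;
          gp[ch+d3] += g * w001;     gp[ch+d1+d3] += g * w101;
          gp[ch+d2+d3] += g * w011;  gp[ch+d1+d2+d3] += g * w111;
          g0 += g * ((1-b)*(1-c)*(v100 - v000) + b*(1-c)*(v110 - v010)
                   + (1-b)*c*(v101 - v001)     + b*c*(v111 - v011));
          g1 += g * ((1-a)*(1-c)*(v010 - v000) + a*(1-c)*(v110 - v100)
                   + (1-a)*c*(v011 - v001)     + a*c*(v111 - v101));
          g2 += g * ((1-a)*(1-b)*(v001 - v000) + a*(1-b)*(v101 - v100)
                   + (1-a)*b*(v011 - v010)     + a*b*(v111 - v110));
        }
        pgu[3 * vox + 0] += g0 * in0;
        pgu[3 * vox + 1] += g1 * in1;
        pgu[3 * vox + 2] += g2 * in2;
      }
}

// [[Rcpp::export]]
NumericVector cpp_integrate_bw(List ic, NumericVector gu) {
  List cache = ic["cache"];
  int steps = as<int>(ic["steps"]);
  int C, n[3];
  NumericVector u0 = cache[0];
  get_dims4(u0, C, n);
  NumericVector g = clone(gu);
  for (int s = steps - 1; s >= 0; --s) {
    NumericVector us = cache[s];
    NumericVector gn(g.size());
    gn.attr("dim") = gu.attr("dim");
    compose_self_bw(us.begin(), g.begin(), gn.begin(), n);
    g = gn;
  }
  double sc = std::pow(2.0, -steps);
  for (R_xlen_t t = 0; t < g.size(); ++t) g[t] *= sc;
  return g;
}

// ----------------------------------------------------- Jacobian determinant --

// Determinant of d(x + u(x))/dx with central differences in the interior and
// one-sided differences on the faces. Identity map gives exactly 1.
// [[Rcpp::export]]
NumericVector cpp_jacdet(NumericVector u) {
  int C, n[3]; get_dims4(u, C, n);
  if (C != 3) stop("displacement field must have 3 channels");
  NumericVector J((R_xlen_t)n[0] * n[1] * n[2]);
  J.attr("dim") = IntegerVector::create(n[0], n[1], n[2]);
  const double* pu = u.begin();
  double* pj = J.begin();
  const R_xlen_t s1 = 3, s2 = (R_xlen_t)3 * n[0], s3 = (R_xlen_t)3 * n[0] * n[1];
  const R_xlen_t st[3] = { s1, s2, s3 };
  for (int k = 0; k < n[2]; ++k)
    for (int j = 0; j < n[1]; ++j)
      for (int i = 0; i < n[0]; ++i) {
        R_xlen_t base = s1 * i + s2 * j + s3 * k;
        int idx3[3] = { i, j, k };
        double M[3][3];
        for (int axis = 0; axis < 3; ++axis) {
          int lo = idx3[axis] > 0 ? -1 : 0;
          int hi = idx3[axis] < n[axis] - 1 ? 1 : 0;
          double denom = (double)(hi - lo);
          if (denom == 0) { // degenerate single-slice axis
            for (int c = 0; c < 3; ++c) M[c][axis] = (c == axis) ? 1.0 : 0.0;
            continue;
          }
          for (int c = 0; c < 3; ++c) {
            double d = (pu[c + base + hi * st[axis]] -
                        pu[c + base + lo * st[axis]]) / denom;
            M[c][axis] = d + (c == axis ? 1.0 : 0.0);
          }
        }
        pj[i + (R_xlen_t)n[0] * (j + (R_xlen_t)n[1] * k)] =
            M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1])
          - M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0])
          + M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
      }
  return J;
}

// ----------------------------------------------------------------- box sum ---

// Separable moving-window sum with window w (odd) and zero padding; windows
// are effectively cropped at the boundary. Self-adjoint. Running-sum
// implementation: O(n) independent of the window size.
// [[Rcpp::export]]
NumericVector cpp_boxsum(NumericVector x, int w) {
  int n[3]; get_dims3(x, n);
  int r = (w - 1) / 2;
  NumericVector cur = clone(x);
  R_xlen_t nline = n[0];
  R_xlen_t nplane = (R_xlen_t)n[0] * n[1];
  // axis 0: scalar running sum along contiguous lines
  {
    NumericVector nxt(x.size()); nxt.attr("dim") = x.attr("dim");
    const double* px = cur.begin(); double* py = nxt.begin();
    for (R_xlen_t line = 0; line < (R_xlen_t)n[1] * n[2]; ++line) {
      const double* lx = px + nline * line;
      double* ly = py + nline * line;
      double run = 0;
      for (int t = 0; t <= std::min(r, n[0] - 1); ++t) run += lx[t];
      for (int i = 0; i < n[0]; ++i) {
        ly[i] = run;
        if (i + r + 1 < n[0]) run += lx[i + r + 1];
        if (i - r >= 0) run -= lx[i - r];
      }
    }
    cur = nxt;
  }
  // axis 1: slide a whole x-row vector along y, per z-plane
  {
    NumericVector nxt(x.size()); nxt.attr("dim") = x.attr("dim");
    const double* px = cur.begin(); double* py = nxt.begin();
    std::vector<double> run(n[0]);
    for (int k = 0; k < n[2]; ++k) {
      const double* pl = px + nplane * k;
      double* ol = py + nplane * k;
      std::fill(run.begin(), run.end(), 0.0);
      for (int t = 0; t <= std::min(r, n[1] - 1); ++t)
        for (int i = 0; i < n[0]; ++i) run[i] += pl[i + nline * t];
      for (int j = 0; j < n[1]; ++j) {
        std::memcpy(ol + nline * j, run.data(), sizeof(double) * n[0]);
        if (j + r + 1 < n[1])
          for (int i = 0; i < n[0]; ++i) run[i] += pl[i + nline * (j + r + 1)];
        if (j - r >= 0)
          for (int i = 0; i < n[0]; ++i) run[i] -= pl[i + nline * (j - r)];
      }
    }
    cur = nxt;
  }
  // axis 2: slide a whole plane vector along z
  {
    NumericVector nxt(x.size()); nxt.attr("dim") = x.attr("dim");
    const double* px = cur.begin(); double* py = nxt.begin();
    std::vector<double> run(nplane, 0.0);
    for (int t = 0; t <= std::min(r, n[2] - 1); ++t)
      for (R_xlen_t i = 0; i < nplane; ++i) run[i] += px[i + nplane * t];
    for (int k = 0; k < n[2]; ++k) {
      std::memcpy(py + nplane * k, run.data(), sizeof(double) * nplane);
      if (k + r + 1 < n[2])
        for (R_xlen_t i = 0; i < nplane; ++i)
          run[i] += px[i + nplane * (k + r + 1)];
      if (k - r >= 0)
        for (R_xlen_t i = 0; i < nplane; ++i)
          run[i] -= px[i + nplane * (k - r)];
    }
    cur = nxt;
  }
  return cur;
}
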