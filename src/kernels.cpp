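#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Volumetric tensors are stored as C x (S*N) matrices: one row per channel,
// columns are voxels of sample 1, then sample 2, ... Spatial linearization
// follows R array order for dims (d0, d1, d2): i = i0 + d0*(i1 + d1*i2),
// with i0 the fastest axis. In the package d0=z (caudal->cranial), d1=row,
// d2=col.

static inline int outDim(int d, int k, int s, int p) {
  return (d + 2 * p - k) / s + 1;
}

// Unfold k0 x k1 x k2 neighbourhoods (stride s, zero pad p) into columns.
// Output is (C*K) x (So*N); row block t*C..t*C+C-1 holds kernel offset
// t = a0 + k0*(a1 + k1*a2).
// [[Rcpp::export]]
NumericMatrix im2col3(const NumericMatrix& x, IntegerVector dims, int n,
                      IntegerVector ksize, IntegerVector stride,
                      IntegerVector pad) {
  const int C = x.nrow();
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  const int S = d0 * d1 * d2;
  const int k0 = ksize[0], k1 = ksize[1], k2 = ksize[2];
  const int s0 = stride[0], s1 = stride[1], s2 = stride[2];
  const int p0 = pad[0], p1 = pad[1], p2 = pad[2];
  const int o0 = outDim(d0, k0, s0, p0);
  const int o1 = outDim(d1, k1, s1, p1);
  const int o2 = outDim(d2, k2, s2, p2);
  const int So = o0 * o1 * o2;
  const int K = k0 * k1 * k2;
  NumericMatrix out(C * K, So * n);
  const double* xp = x.begin();
  double* op = out.begin();
  const int outNrow = C * K;
  for (int b = 0; b < n; ++b) {
    const double* xb = xp + (R_xlen_t)b * S * C;
    for (int j2 = 0; j2 < o2; ++j2) {
      for (int j1 = 0; j1 < o1; ++j1) {
        const R_xlen_t colBase =
          (R_xlen_t)(o0 * (j1 + o1 * j2) + b * So) * outNrow;
        for (int a2 = 0; a2 < k2; ++a2) {
          const int i2 = j2 * s2 - p2 + a2;
          const bool out2 = (i2 < 0 || i2 >= d2);
          for (int a1 = 0; a1 < k1; ++a1) {
            const int i1 = j1 * s1 - p1 + a1;
            const bool outPlane = out2 || i1 < 0 || i1 >= d1;
            for (int a0 = 0; a0 < k0; ++a0) {
              const int t = a0 + k0 * (a1 + k1 * a2);
              double* dst0 = op + colBase + (R_xlen_t)t * C;
              if (outPlane) {
                for (int j0 = 0; j0 < o0; ++j0)
                  std::memset(dst0 + (R_xlen_t)j0 * outNrow, 0,
                              sizeof(double) * C);
                continue;
              }
              // i0 = j0*s0 - p0 + a0 must lie in [0, d0)
              int j0lo, j0hi; // valid inclusive range
              if (s0 == 1) {
                j0lo = p0 - a0; if (j0lo < 0) j0lo = 0;
                j0hi = d0 - 1 - a0 + p0; if (j0hi > o0 - 1) j0hi = o0 - 1;
              } else {
                j0lo = 0; while (j0lo < o0 && j0lo * s0 - p0 + a0 < 0) ++j0lo;
                j0hi = o0 - 1;
                while (j0hi >= 0 && j0hi * s0 - p0 + a0 >= d0) --j0hi;
              }
              const R_xlen_t rowOff = (R_xlen_t)(d0 * (i1 + d1 * i2)) * C;
              for (int j0 = 0; j0 < j0lo && j0 < o0; ++j0)
                std::memset(dst0 + (R_xlen_t)j0 * outNrow, 0,
                            sizeof(double) * C);
              for (int j0 = j0lo; j0 <= j0hi; ++j0) {
                const int i0 = j0 * s0 - p0 + a0;
                const double* src = xb + rowOff + (R_xlen_t)i0 * C;
                double* dst = dst0 + (R_xlen_t)j0 * outNrow;
                for (int c = 0; c < C; ++c) dst[c] = src[c];
              }
              for (int j0 = (j0hi < -1 ? 0 : j0hi + 1); j0 < o0; ++j0)
                std::memset(dst0 + (R_xlen_t)j0 * outNrow, 0,
                            sizeof(double) * C);
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: fold columns back with accumulation.
// [[Rcpp::export]]
NumericMatrix col2im3(const NumericMatrix& cols, int C, IntegerVector dims,
                      int n, IntegerVector ksize, IntegerVector stride,
                      IntegerVector pad) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  const int S = d0 * d1 * d2;
  const int k0 = ksize[0], k1 = ksize[1], k2 = ksize[2];
  const int s0 = stride[0], s1 = stride[1], s2 = stride[2];
  const int p0 = pad[0], p1 = pad[1], p2 = pad[2];
  const int o0 = outDim(d0, k0, s0, p0);
  const int o1 = outDim(d1, k1, s1, p1);
  const int o2 = outDim(d2, k2, s2, p2);
  const int So = o0 * o1 * o2;
  const int K = k0 * k1 * k2;
  if (cols.nrow() != C * K || cols.ncol() != So * n)
    stop("col2im3: column matrix has unexpected shape");
  NumericMatrix x(C, S * n);
  const double* cp = cols.begin();
  double* xp = x.begin();
  const int colsNrow = C * K;
  for (int b = 0; b < n; ++b) {
    double* xb = xp + (R_xlen_t)b * S * C;
    for (int j2 = 0; j2 < o2; ++j2) {
      for (int j1 = 0; j1 < o1; ++j1) {
        const R_xlen_t colBase =
          (R_xlen_t)(o0 * (j1 + o1 * j2) + b * So) * colsNrow;
        for (int a2 = 0; a2 < k2; ++a2) {
          const int i2 = j2 * s2 - p2 + a2;
          if (i2 < 0 || i2 >= d2) continue;
          for (int a1 = 0; a1 < k1; ++a1) {
            const int i1 = j1 * s1 - p1 + a1;
            if (i1 < 0 || i1 >= d1) continue;
            for (int a0 = 0; a0 < k0; ++a0) {
              const int t = a0 + k0 * (a1 + k1 * a2);
              int j0lo, j0hi;
              if (s0 == 1) {
                j0lo = p0 - a0; if (j0lo < 0) j0lo = 0;
                j0hi = d0 - 1 - a0 + p0; if (j0hi > o0 - 1) j0hi = o0 - 1;
              } else {
                j0lo = 0; while (j0lo < o0 && j0lo * s0 - p0 + a0 < 0) ++j0lo;
                j0hi = o0 - 1;
                while (j0hi >= 0 && j0hi * s0 - p0 + a0 >= d0) --j0hi;
              }
              const R_xlen_t rowOff = (R_xlen_t)(d0 * (i1 + d1 * i2)) * C;
              const double* src0 = cp + colBase + (R_xlen_t)t * C;
              for (int j0 = j0lo; j0 <= j0hi; ++j0) {
                const int i0 = j0 * s0 - p0 + a0;
                const double* src = src0 + (R_xlen_t)j0 * colsNrow;
                double* dst = xb + rowOff + (R_xlen_t)i0 * C;
                for (int c = 0; c < C; ++c) dst[c] += src[c];
              }
            }
          }
        }
      }
    }
  }
  return x;
}

// Max pooling, no padding. Returns pooled values and the 0-based input
// column index of each argmax (for the backward scatter).
// [[Rcpp::export]]
List maxpool3_fwd(const NumericMatrix& x, IntegerVector dims, int n,
                  IntegerVector ksize, IntegerVector stride) {
  const int C = x.nrow();
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  const int S = d0 * d1 * d2;
  const int k0 = ksize[0], k1 = ksize[1], k2 = ksize[2];
  const int s0 = stride[0], s1 = stride[1], s2 = stride[2];
  const int o0 = outDim(d0, k0, s0, 0);
  const int o1 = outDim(d1, k1, s1, 0);
  const int o2 = outDim(d2, k2, s2, 0);
  const int So = o0 * o1 * o2;
  NumericMatrix y(C, So * n);
  IntegerMatrix idx(C, So * n);
  const double* xp = x.begin();
  for (int b = 0; b < n; ++b) {
    for (int j2 = 0; j2 < o2; ++j2) {
      for (int j1 = 0; j1 < o1; ++j1) {
        for (int j0 = 0; j0 < o0; ++j0) {
          const int jcol = j0 + o0 * (j1 + o1 * j2) + b * So;
          for (int c = 0; c < C; ++c) {
            double best = R_NegInf;
            int besti = -1;
            for (int a2 = 0; a2 < k2; ++a2) {
              const int i2 = j2 * s2 + a2;
              if (i2 >= d2) continue;
              for (int a1 = 0; a1 < k1; ++a1) {
                const int i1 = j1 * s1 + a1;
                if (i1 >= d1) continue;
                for (int a0 = 0; a0 < k0; ++a0) {
                  const int i0 = j0 * s0 + a0;
                  if (i0 >= d0) continue;
                  const int icol = i0 + d0 * (i1 + d1 * i2) + b * S;
                  const double v = xp[(R_xlen_t)icol * C + c];
                  if (v > best) { best = v; besti = icol; }
                }
              }
            }
            y(c, jcol) = best;
            idx(c, jcol) = besti;
          }
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix maxpool3_bwd(const NumericMatrix& dy, const IntegerMatrix& idx,
                           int ncolIn) {
  const int C = dy.nrow();
  NumericMatrix dx(C, ncolIn);
  for (int j = 0; j < dy.ncol(); ++j)
    for (int c = 0; c < C; ++c)
      dx(c, idx(c, j)) += dy(c, j);
  return dx;
}

// 3D connected-component labelling by breadth-first search.
// connectivity: 6, 18 or 26. mask: integer/logical vector of length
// d0*d1*d2 (R array order). Returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector cclabel3(const IntegerVector& mask, IntegerVector dims,
                       int connectivity) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  const R_xlen_t S = (R_xlen_t)d0 * d1 * d2;
  if (mask.size() != S) stop("cclabel3: mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("cclabel3: connectivity must be 6, 18 or 26");
  // neighbour offsets
  std::vector<int> n0, n1, n2;
  for (int a2 = -1; a2 <= 1; ++a2)
    for (int a1 = -1; a1 <= 1; ++a1)
      for (int a0 = -1; a0 <= 1; ++a0) {
        const int nz = std::abs(a0) + std::abs(a1) + std::abs(a2);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        n0.push_back(a0); n1.push_back(a1); n2.push_back(a2);
      }
  IntegerVector labels(S, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t seed = 0; seed < S; ++seed) {
    if (mask[seed] == 0 || labels[seed] != 0) continue;
    ++next;
    labels[seed] = next;
    stack.push_back(seed);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int i0 = (int)(cur % d0);
      const int i1 = (int)((cur / d0) % d1);
      const int i2 = (int)(cur / ((R_xlen_t)d0 * d1));
      for (size_t t = 0; t < n0.size(); ++t) {
        const int q0 = i0 + n0[t], q1 = i1 + n1[t], q2 = i2 + n2[t];
        if (q0 < 0 || q0 >= d0 || q1 < 0 || q1 >= d1 || q2 < 0 || q2 >= d2)
          continue;
        const R_xlen_t q = q0 + (R_xlen_t)d0 * (q1 + (R_xlen_t)d1 * q2);
        if (mask[q] != 0 && labels[q] == 0) {
          labels[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  labels.attr("n_components") = next;
  return labels;
}
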