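// Same-padding convolution kernels.  Feature maps are (N*H*W) x C
// column-major matrices.  The geometry is a list of k^2 kernel offsets;
// each offset carries `runs`, a run-length encoding (1-based dstart,
// sstart, len) of its injective output-row -> input-row map.  Long runs
// (stride-1 offsets with no vertical shift) go straight to strided BLAS
// dgemm on the original storage; short runs (strided convolutions,
// vertically shifted offsets) are memcpy-packed into a compact buffer for
// a single dgemm.  No im2col temporaries are ever materialized.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>
#include <vector>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

static const double ONE = 1.0;
static const double ZERO = 0.0;

// pack rows of x described by `runs` (column `which`: 0 = dstart,
// 1 = sstart) into the compact n x c buffer
static void pack_runs(const double* x, int ldx, int c,
                      const IntegerMatrix& runs, int which, int n,
                      double* buf) {
  const int nr = runs.nrow();
  for (int j = 0; j < c; ++j) {
    const double* src = x + (size_t)j * ldx;
    double* dst = buf + (size_t)j * n;
    int pos = 0;
    for (int r = 0; r < nr; ++r) {
      const int s0 = runs(r, which), L = runs(r, 2);
      std::memcpy(dst + pos, src + s0 - 1, (size_t)L * sizeof(double));
      pos += L;
    }
  }
}

// add the compact n x c buffer back into rows of y described by `runs`
static void unpack_add_runs(double* y, int ldy, int c,
                            const IntegerMatrix& runs, int which, int n,
                            const double* buf) {
  const int nr = runs.nrow();
  for (int j = 0; j < c; ++j) {
    const double* src = buf + (size_t)j * n;
    double* dst = y + (size_t)j * ldy;
    int pos = 0;
    for (int r = 0; r < nr; ++r) {
      const int d0 = runs(r, which), L = runs(r, 2);
      const double* s = src + pos;
      double* d = dst + d0 - 1;
      for (int l = 0; l < L; ++l) d[l] += s[l];
      pos += L;
    }
  }
}

// pack into a compact buffer when runs are short, where per-run dgemm
// call overhead dominates
static bool use_pack(const IntegerMatrix& runs, int n) {
  return n <= runs.nrow() || (n / runs.nrow() < 192);
}

// y (rout x cout) += sum_o x[runs_o] %*% W[o block, ]
// [[Rcpp::export]]
NumericMatrix cpp_conv_fwd(const NumericMatrix& x, const NumericMatrix& Wm,
                           const List& offs, int rout) {
  const int cin = x.ncol();
  const int rin = x.nrow();
  const int cout = Wm.ncol();
  const int ldw = Wm.nrow();            // k2 * cin
  NumericMatrix y(rout, cout);
  const double* xp = x.begin();
  const double* wp = Wm.begin();
  double* yp = y.begin();
  std::vector<double> bufx, bufy;
  for (int o = 0; o < offs.size(); ++o) {
    List off = offs[o];
    IntegerMatrix runs = off["runs"];
    IntegerVector ri = off["ri"];
    const int n = ri.size();
    const double* wo = wp + (size_t)o * cin;
    if (use_pack(runs, n)) {
      bufx.resize((size_t)n * cin);
      bufy.resize((size_t)n * cout);
      pack_runs(xp, rin, cin, runs, 1, n, bufx.data());
      F77_CALL(dgemm)("N", "N", &n, &cout, &cin, &ONE,
                      bufx.data(), &n, wo, &ldw, &ZERO,
                      bufy.data(), &n FCONE FCONE);
      unpack_add_runs(yp, rout, cout, runs, 0, n, bufy.data());
    } else {
      const int nr = runs.nrow();
      for (int r = 0; r < nr; ++r) {
        const int d0 = runs(r, 0), s0 = runs(r, 1), L = runs(r, 2);
        F77_CALL(dgemm)("N", "N", &L, &cout, &cin, &ONE,
                        xp + s0 - 1, &rin, wo, &ldw, &ONE,
                        yp + d0 - 1, &rout FCONE FCONE);
      }
    }
  }
  return y;
}

// dW (k2*cin x cout) += sum_runs t(x[run]) %*% dy[run]
// [[Rcpp::export]]
NumericMatrix cpp_conv_dw(const NumericMatrix& x, const NumericMatrix& dy,
                          const List& offs) {
  const int cin = x.ncol();
  const int rin = x.nrow();
  const int cout = dy.ncol();
  const int rout = dy.nrow();
  const int k2 = offs.size();
  const int ldw = k2 * cin;
  NumericMatrix dW(ldw, cout);
  const double* xp = x.begin();
  const double* dp = dy.begin();
  double* wp = dW.begin();
  std::vector<double> bufx, bufd;
  for (int o = 0; o < k2; ++o) {
    List off = offs[o];
    IntegerMatrix runs = off["runs"];
    IntegerVector ri = off["ri"];
    const int n = ri.size();
    double* wo = wp + (size_t)o * cin;
    if (use_pack(runs, n)) {
      bufx.resize((size_t)n * cin);
      bufd.resize((size_t)n * cout);
      pack_runs(xp, rin, cin, runs, 1, n, bufx.data());
      pack_runs(dp, rout, cout, runs, 0, n, bufd.data());
      F77_CALL(dgemm)("T", "N", &cin, &cout, &n, &ONE,
                      bufx.data(), &n, bufd.data(), &n, &ONE,
                      wo, &ldw FCONE FCONE);
    } else {
      const int nr = runs.nrow();
      for (int r = 0; r < nr; ++r) {
        const int d0 = runs(r, 0), s0 = runs(r, 1), L = runs(r, 2);
        F77_CALL(dgemm)("T", "N", &cin, &cout, &L, &ONE,
                        xp + s0 - 1, &rin, dp + d0 - 1, &rout, &ONE,
                        wo, &ldw FCONE FCONE);
      }
    }
  }
  return dW;
}

// dx (rin x cin) += sum_runs dy[run] %*% t(W[o block, ])
// [[Rcpp::export]]
NumericMatrix cpp_conv_dx(const NumericMatrix& dy, const NumericMatrix& Wm,
                          const List& offs, int rin) {
  const int cout = dy.ncol();
  const int rout = dy.nrow();
  const int ldw = Wm.nrow();            // k2 * cin
  const int cin = ldw / offs.size();
  NumericMatrix dx(rin, cin);
  const double* dp = dy.begin();
  const double* wp = Wm.begin();
  double* op = dx.begin();
  std::vector<double> bufd, bufo;
  for (int o = 0; o < offs.size(); ++o) {
    List off = offs[o];
    IntegerMatrix runs = off["runs"];
    IntegerVector ri = off["ri"];
    const int n = ri.size();
    const double* wo = wp + (size_t)o * cin;
    if (use_pack(runs, n)) {
      bufd.resize((size_t)n * cout);
      bufo.resize((size_t)n * cin);
      pack_runs(dp, rout, cout, runs, 0, n, bufd.data());
      F77_CALL(dgemm)("N", "T", &n, &cin, &cout, &ONE,
                      bufd.data(), &n, wo, &ldw, &ZERO,
                      bufo.data(), &n FCONE FCONE);
      unpack_add_runs(op, rin, cin, runs, 1, n, bufo.data());
    } else {
      const int nr = runs.nrow();
      for (int r = 0; r < nr; ++r) {
        const int d0 = runs(r, 0), s0 = runs(r, 1), L = runs(r, 2);
        F77_CALL(dgemm)("N", "T", &L, &cin, &cout, &ONE,
                        dp + d0 - 1, &rout, wo, &ldw, &ONE,
                        op + s0 - 1, &rin FCONE FCONE);
      }
    }
  }
  return dx;
}

// 2x2 stride-2 max pooling: returns pooled values and the winning input
// row (1-based) per pooled cell and channel, for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool(const NumericMatrix& x, const IntegerMatrix& idx4) {
  const int rout = idx4.nrow();
  const int cch = x.ncol();
  const int rin = x.nrow();
  NumericMatrix y(rout, cch);
  IntegerMatrix win(rout, cch);
  const double* xp = x.begin();
  for (int c = 0; c < cch; ++c) {
    const double* src = xp + (size_t)c * rin;
    for (int j = 0; j < rout; ++j) {
      int best = idx4(j, 0);
      double bv = src[best - 1];
      for (int q = 1; q < 4; ++q) {
        int i = idx4(j, q);
        double v = src[i - 1];
        if (v > bv) { bv = v; best = i; }
      }
      y(j, c) = bv;
      win(j, c) = best;
    }
  }
  return List::create(_["y"] = y, _["win"] = win);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(const NumericMatrix& dy,
                              const IntegerMatrix& win, int rin) {
  const int rout = dy.nrow();
  const int cch = dy.ncol();
  NumericMatrix dx(rin, cch);
  for (int c = 0; c < cch; ++c) {
    for (int j = 0; j < rout; ++j) dx(win(j, c) - 1, c) += dy(j, c);
  }
  return dx;
}

// fused elementwise helpers -------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_lrelu(const NumericMatrix& x, double slope) {
  NumericMatrix y(x.nrow(), x.ncol());
  const double* xp = x.begin(); double* yp = y.begin();
  const size_t n = (size_t)x.nrow() * x.ncol();
  for (size_t i = 0; i < n; ++i) {
    const double v = xp[i];
    yp[i] = v > 0 ? v : slope * v;
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_lrelu_bwd(const NumericMatrix& d, const NumericMatrix& x,
                            double slope) {
  NumericMatrix dx(d.nrow(), d.ncol());
  const double* dp = d.begin(); const double* xp = x.begin();
  double* op = dx.begin();
  const size_t n = (size_t)d.nrow() * d.ncol();
  for (size_t i = 0; i < n; ++i) op[i] = xp[i] > 0 ? dp[i] : slope * dp[i];
  return dx;
}

// per-column affine map y = x * sc[col] + off[col]
// [[Rcpp::export]]
NumericMatrix cpp_colscale(const NumericMatrix& x, const NumericVector& sc,
                           const NumericVector& off) {
  const int r = x.nrow(), c = x.ncol();
  NumericMatrix y(r, c);
  const double* xp = x.begin(); double* yp = y.begin();
  for (int j = 0; j < c; ++j) {
    const double s = sc[j], o = off[j];
    const double* src = xp + (size_t)j * r;
    double* dst = yp + (size_t)j * r;
    for (int i = 0; i < r; ++i) dst[i] = src[i] * s + o;
  }
  return y;
}

// column means and population variances in one pass
// [[Rcpp::export]]
List cpp_colstats(const NumericMatrix& x) {
  const int r = x.nrow(), c = x.ncol();
  NumericVector mu(c), va(c);
  const double* xp = x.begin();
  for (int j = 0; j < c; ++j) {
    const double* src = xp + (size_t)j * r;
    double s = 0, s2 = 0;
    for (int i = 0; i < r; ++i) { s += src[i]; s2 += src[i] * src[i]; }
    const double m = s / r;
    mu[j] = m;
    va[j] = s2 / r - m * m;
  }
  return List::create(_["mu"] = mu, _["va"] = va);
}

// batch-norm backward (batch statistics):
// dx = istd * (dxh - mean(dxh) - xh * mean(dxh * xh)), dxh = d * g
// also returns dg = colSums(d * xh) and db = colSums(d)
// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& d, const NumericMatrix& xh,
                const NumericVector& g, const NumericVector& istd) {
  const int r = d.nrow(), c = d.ncol();
  NumericMatrix dx(r, c);
  NumericVector dg(c), db(c);
  const double* dp = d.begin(); const double* hp = xh.begin();
  double* op = dx.begin();
  for (int j = 0; j < c; ++j) {
    const double* dj = dp + (size_t)j * r;
    const double* hj = hp + (size_t)j * r;
    double* oj = op + (size_t)j * r;
    double s1 = 0, s2 = 0, sg = 0, sb = 0;
    const double gj = g[j];
    for (int i = 0; i < r; ++i) {
      const double dh = dj[i] * gj;
      s1 += dh;
      s2 += dh * hj[i];
      sg += dj[i] * hj[i];
      sb += dj[i];
    }
    dg[j] = sg; db[j] = sb;
    const double m1 = s1 / r, m2 = s2 / r, is = istd[j];
    for (int i = 0; i < r; ++i)
      oj[i] = is * (dj[i] * gj - m1 - hj[i] * m2);
  }
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}

// Adam update: m, v are modified in place (they are private optimizer
// state); returns the updated parameter array.
// [[Rcpp::export]]
NumericVector cpp_adam(const NumericVector& p, const NumericVector& g,
                       NumericVector m, NumericVector v, double lr,
                       double b1, double b2, double bc1, double bc2,
                       double eps) {
  const R_xlen_t n = p.size();
  NumericVector out(n);
  out.attr("dim") = p.attr("dim");
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1 - b1) * g[i];
    v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
    out[i] = p[i] - lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
  }
  return out;
}

#include <malloc.h>

// Keep large freed blocks in the process heap instead of returning them to
// the OS: training allocates and frees many multi-megabyte feature maps per
// cycle, and the default mmap-per-allocation policy spends more time in
// page faults than in arithmetic.  Called from .onLoad.
// [[Rcpp::export]]
void cpp_tune_malloc() {
#ifdef M_MMAP_THRESHOLD
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}
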