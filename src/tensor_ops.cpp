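// Low-level tensor primitives for the vein-verification network.
// Layout conventions (R column-major):
//   activations: H x W x C x N
//   conv weights: K x K x (Cin/groups) x Cout
// Convolutions are computed by im2col + BLAS GEMM, one group at a time, in
// single precision internally (the reduction depth per output element is a
// few thousand at most, so float accumulation is ample for training, and it
// halves the memory traffic of the im2col buffer). The buffer is stored
// positions-by-taps, so that for stride-1 convolutions each column is a
// contiguous run of the input.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill (mode 0) the (N*Ho*Wo) x (K*K*Cg) buffer for one group, or
// scatter-add it back into dx (mode 1). Buffer column (kh, kw, c) holds
// x[ho*stride + kh - pad, wo*stride + kw - pad, c] over positions ordered
// ho fastest, then wo, then n.
static void im2colT_group(const double* xp, float* colp,
                          int H, int W, int Cin, int N,
                          int K, int stride, int pad,
                          int Cg, int g, int Ho, int Wo,
                          bool accumulate, double* dxp) {
  const long plane = (long)H * W;
  const long npos = (long)N * Ho * Wo;
  long j = 0;  // buffer column index
  for (int c = 0; c < Cg; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      const int dw = kw - pad;
      for (int kh = 0; kh < K; ++kh) {
        const int dh = kh - pad;
        float* cc = colp + npos * (j++);
        long pos = 0;
        for (int n = 0; n < N; ++n) {
          const double* xn = xp + plane * ((long)Cin * n + (long)Cg * g + c);
          double* dxn = accumulate ?
            dxp + plane * ((long)Cin * n + (long)Cg * g + c) : nullptr;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + dw;
            if (wi < 0 || wi >= W) {
              if (!accumulate) std::memset(cc + pos, 0, sizeof(float) * Ho);
              pos += Ho;
              continue;
            }
            if (stride == 1) {
              const int lo = std::max(0, -dh);
              const int hi = std::min(Ho, H - dh);
              if (!accumulate) {
                for (int ho = 0; ho < lo; ++ho) cc[pos + ho] = 0.0f;
                const double* src = xn + (long)H * wi + dh;
                for (int ho = lo; ho < hi; ++ho)
                  cc[pos + ho] = (float)src[ho];
                for (int ho = hi; ho < Ho; ++ho) cc[pos + ho] = 0.0f;
              } else if (hi > lo) {
                double* dst = dxn + (long)H * wi + dh;
                const float* src = cc + pos;
                for (int ho = lo; ho < hi; ++ho) dst[ho] += src[ho];
              }
              pos += Ho;
            } else {
              for (int ho = 0; ho < Ho; ++ho, ++pos) {
                const int hi2 = ho * stride + dh;
                if (hi2 >= 0 && hi2 < H) {
                  if (accumulate) dxn[(long)H * wi + hi2] += cc[pos];
                  else cc[pos] = (float)xn[(long)H * wi + hi2];
                } else if (!accumulate) {
                  cc[pos] = 0.0f;
                }
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd_cpp")]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int K = wd[0], Cg = wd[2], Cout = wd[3];
  if (wd[1] != K) stop("conv kernel must be square");
  if (Cin % Cg != 0) stop("input channels not divisible by kernel depth");
  const int groups = Cin / Cg;
  if (Cout % groups != 0) stop("output channels not divisible by groups");
  const int Coutg = Cout / groups;
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  const long HoWo = (long)Ho * Wo;
  const long npos = (long)N * HoWo;

  NumericVector out(HoWo * Cout * (long)N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double* op = out.begin();

  const long rows = (long)K * K * Cg;
  arma::fmat colT(npos, rows);
  for (int g = 0; g < groups; ++g) {
    im2colT_group(x.begin(), colT.memptr(), H, W, Cin, N, K, stride, pad,
                  Cg, g, Ho, Wo, false, nullptr);
    arma::fmat Wmat(rows, Coutg);
    const double* wg = w.begin() + rows * Coutg * g;
    for (long i = 0; i < rows * Coutg; ++i) Wmat.memptr()[i] = (float)wg[i];
    arma::fmat outg = colT * Wmat;  // npos x Coutg
    for (int oc = 0; oc < Coutg; ++oc) {
      const float* src = outg.colptr(oc);
      for (int n = 0; n < N; ++n) {
        double* dst = op + HoWo * ((long)g * Coutg + oc + (long)Cout * n);
        const float* s2 = src + HoWo * n;
        for (long i = 0; i < HoWo; ++i) dst[i] = s2[i];
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd_cpp")]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dout,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int K = wd[0], Cg = wd[2], Cout = wd[3];
  const int groups = Cin / Cg;
  const int Coutg = Cout / groups;
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  const long HoWo = (long)Ho * Wo;
  const long npos = (long)N * HoWo;

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  const double* dop = dout.begin();

  const long rows = (long)K * K * Cg;
  arma::fmat colT(npos, rows);
  arma::fmat doutg(npos, Coutg);
  for (int g = 0; g < groups; ++g) {
    im2colT_group(x.begin(), colT.memptr(), H, W, Cin, N, K, stride, pad,
                  Cg, g, Ho, Wo, false, nullptr);
    for (int oc = 0; oc < Coutg; ++oc) {
      float* dst = doutg.colptr(oc);
      for (int n = 0; n < N; ++n) {
        const double* src = dop + HoWo * ((long)g * Coutg + oc +
                                          (long)Cout * n);
        float* d2 = dst + HoWo * n;
        for (long i = 0; i < HoWo; ++i) d2[i] = (float)src[i];
      }
    }
    arma::fmat dWg = colT.t() * doutg;  // (K*K*Cg) x Coutg
    double* dwp = dw.begin() + rows * Coutg * g;
    for (long i = 0; i < rows * Coutg; ++i) dwp[i] = dWg.memptr()[i];
    arma::fmat Wmat(rows, Coutg);
    const double* wg = w.begin() + rows * Coutg * g;
    for (long i = 0; i < rows * Coutg; ++i) Wmat.memptr()[i] = (float)wg[i];
    colT = doutg * Wmat.t();  // reuse buffer as d(colT)
    im2colT_group(nullptr, colT.memptr(), H, W, Cin, N, K, stride, pad,
                  Cg, g, Ho, Wo, true, dx.begin());
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export(name = ".maxpool_fwd_cpp")]]
List maxpool_fwd_cpp(NumericVector x, int K, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  const long HoWo = (long)Ho * Wo;
  NumericVector out(HoWo * C * (long)N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector idx(out.size());  // 1-based linear index into x
  idx.attr("dim") = out.attr("dim");
  const double* xp = x.begin();
  double* op = out.begin();
  double* ip = idx.begin();
  long o = 0;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* plane = xp + (long)H * W * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * stride - pad, w0 = wo * stride - pad;
        double best = R_NegInf;
        long bi = -1;
        for (int kw = 0; kw < K; ++kw) {
          const int wi = w0 + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            const int hi = h0 + kh;
            if (hi < 0 || hi >= H) continue;
            const double v = plane[hi + (long)H * wi];
            if (v > best) { best = v; bi = hi + (long)H * wi; }
          }
        }
        op[o] = best;
        ip[o] = (double)((long)H * W * cn + bi + 1);
        ++o;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd_cpp")]]
NumericVector maxpool_bwd_cpp(NumericVector dout, NumericVector idx,
                              IntegerVector xdim) {
  NumericVector dx((long)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dop = dout.begin();
  const double* ip = idx.begin();
  const long n = dout.size();
  for (long i = 0; i < n; ++i) dxp[(long)ip[i] - 1] += dop[i];
  return dx;
}

// Per-channel sum and sum of squares over (H, W, N).
// [[Rcpp::export(name = ".channel_stats_cpp")]]
List channel_stats_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const long plane = (long)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector s(C), q(C);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* p = xp + plane * ((long)C * n + c);
      double a = 0, b = 0;
      for (long i = 0; i < plane; ++i) { a += p[i]; b += p[i] * p[i]; }
      s[c] += a; q[c] += b;
    }
  }
  return List::create(_["sum"] = s, _["sumsq"] = q);
}

// y = x * scale[c] + shift[c], per channel.
// [[Rcpp::export(name = ".scale_shift_cpp")]]
NumericVector scale_shift_cpp(NumericVector x, NumericVector scale,
                              NumericVector shift) {
  IntegerVector xd = x.attr("dim");
  const long plane = (long)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const long off = plane * ((long)C * n + c);
      const double sc = scale[c], sh = shift[c];
      for (long i = 0; i < plane; ++i) yp[off + i] = xp[off + i] * sc + sh;
    }
  }
  return y;
}

// Full batch-norm backward. Training mode propagates through the batch
// statistics; eval mode treats them as constants.
// [[Rcpp::export(name = ".bn_bwd_cpp")]]
List bn_bwd_cpp(NumericVector dout, NumericVector x, NumericVector mu,
                NumericVector invstd, NumericVector gamma, bool training) {
  IntegerVector xd = x.attr("dim");
  const long plane = (long)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  const double M = (double)plane * N;
  NumericVector dgamma(C), dbeta(C);
  const double* xp = x.begin();
  const double* dp = dout.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const long off = plane * ((long)C * n + c);
      const double m = mu[c], is = invstd[c];
      double a = 0, b = 0;
      for (long i = 0; i < plane; ++i) {
        a += dp[off + i];
        b += dp[off + i] * (xp[off + i] - m) * is;
      }
      dbeta[c] += a; dgamma[c] += b;
    }
  }
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const long off = plane * ((long)C * n + c);
      const double m = mu[c], is = invstd[c], g = gamma[c];
      if (training) {
        const double s1 = dbeta[c], s2 = dgamma[c];
        const double k = g * is / M;
        for (long i = 0; i < plane; ++i) {
          const double xhat = (xp[off + i] - m) * is;
          dxp[off + i] = k * (M * dp[off + i] - s1 - xhat * s2);
        }
      } else {
        const double k = g * is;
        for (long i = 0; i < plane; ++i) dxp[off + i] = k * dp[off + i];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".relu_fwd_cpp")]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  const long n = x.size();
  for (long i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// dout gated by the forward output (zero where the unit was inactive).
// [[Rcpp::export(name = ".relu_bwd_cpp")]]
NumericVector relu_bwd_cpp(NumericVector dout, NumericVector out) {
  NumericVector dx(dout.size());
  dx.attr("dim") = dout.attr("dim");
  const double* dp = dout.begin();
  const double* op = out.begin();
  double* xp = dx.begin();
  const long n = dout.size();
  for (long i = 0; i < n; ++i) xp[i] = op[i] > 0 ? dp[i] : 0.0;
  return dx;
}

// Batched scale-attention core. ro, rt, f: (H, W, C, N) arrays viewed as
// (HW, C) matrices per sample (the flattenings coincide). Returns the
// refined features plus the per-sample descriptor and aggregation needed by
// the backward pass.
// [[Rcpp::export(name = ".sa_fwd_cpp")]]
List sa_fwd_cpp(NumericVector ro, NumericVector rt, NumericVector f,
                double gate) {
  IntegerVector d = f.attr("dim");
  const long HW = (long)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector out(f.size()); out.attr("dim") = d;
  NumericVector phis((long)C * C * N);
  phis.attr("dim") = IntegerVector::create(C, C, N);
  NumericVector Ms(f.size()); Ms.attr("dim") = d;
  for (int n = 0; n < N; ++n) {
    const arma::mat O(const_cast<double*>(ro.begin()) + HW * C * n,
                      HW, C, false, true);
    const arma::mat T(const_cast<double*>(rt.begin()) + HW * C * n,
                      HW, C, false, true);
    arma::mat phi(phis.begin() + (long)C * C * n, C, C, false, true);
    phi = O.t() * T;
    for (int r = 0; r < C; ++r) {      // row softmax
      double mx = phi(r, 0);
      for (int c = 1; c < C; ++c) mx = std::max(mx, phi(r, c));
      double s = 0;
      for (int c = 0; c < C; ++c) { phi(r, c) = std::exp(phi(r, c) - mx); s += phi(r, c); }
      for (int c = 0; c < C; ++c) phi(r, c) /= s;
    }
    const arma::mat F(const_cast<double*>(f.begin()) + HW * C * n,
                      HW, C, false, true);
    arma::mat M(Ms.begin() + HW * C * n, HW, C, false, true);
    M = F * phi.t();
    arma::mat Y(out.begin() + HW * C * n, HW, C, false, true);
    Y = F + gate * M;
  }
  return List::create(_["out"] = out, _["phis"] = phis, _["Ms"] = Ms);
}

// [[Rcpp::export(name = ".sa_bwd_cpp")]]
List sa_bwd_cpp(NumericVector dout, NumericVector f, NumericVector ro,
                NumericVector rt, NumericVector phis, NumericVector Ms,
                double gate) {
  IntegerVector d = f.attr("dim");
  const long HW = (long)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector df(f.size()); df.attr("dim") = d;
  NumericVector dom(f.size()); dom.attr("dim") = d;
  NumericVector dth(f.size()); dth.attr("dim") = d;
  double dgate = 0;
  for (int n = 0; n < N; ++n) {
    const arma::mat dO(const_cast<double*>(dout.begin()) + HW * C * n,
                       HW, C, false, true);
    const arma::mat F(const_cast<double*>(f.begin()) + HW * C * n,
                      HW, C, false, true);
    const arma::mat O(const_cast<double*>(ro.begin()) + HW * C * n,
                      HW, C, false, true);
    const arma::mat T(const_cast<double*>(rt.begin()) + HW * C * n,
                      HW, C, false, true);
    const arma::mat phi(const_cast<double*>(phis.begin()) + (long)C * C * n,
                        C, C, false, true);
    const arma::mat M(const_cast<double*>(Ms.begin()) + HW * C * n,
                      HW, C, false, true);
    dgate += arma::accu(dO % M);
    arma::mat dphi = gate * (dO.t() * F);
    arma::mat dF(df.begin() + HW * C * n, HW, C, false, true);
    dF = dO + gate * (dO * phi);
    arma::vec rs = arma::sum(dphi % phi, 1);
    arma::mat dS = phi % (dphi.each_col() - rs);
    arma::mat dOm(dom.begin() + HW * C * n, HW, C, false, true);
    dOm = T * dS.t();
    arma::mat dTh(dth.begin() + HW * C * n, HW, C, false, true);
    dTh = O * dS;
  }
  return List::create(_["df"] = df, _["domega"] = dom, _["dtheta"] = dth,
                      _["dgate"] = dgate);
}
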