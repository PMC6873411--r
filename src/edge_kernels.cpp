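// Hot kernels for edge-list message passing. The autodiff layer calls these
// for the gather-multiply-scatter aggregation over directed edges; doing it
// in compiled code avoids materializing edge-major temporaries in R.
#include <Rcpp.h>
using namespace Rcpp;

// out[dst[e], ] += w[e] * X[src[e], ] over all directed edges e.
// [[Rcpp::export]]
NumericMatrix edge_scatter(NumericMatrix X, NumericVector w,
                           IntegerVector src, IntegerVector dst, int n_out) {
  const int N = src.size(), h = X.ncol(), nr = X.nrow();
  NumericMatrix out(n_out, h);
  const double* xp = X.begin();
  const double* wp = w.begin();
  const int* sp = src.begin();
  const int* dp = dst.begin();
  double* op = out.begin();
  for (int c = 0; c < h; ++c) {
    const double* xc = xp + (size_t)c * nr;
    double* oc = op + (size_t)c * n_out;
    for (int e = 0; e < N; ++e) oc[dp[e] - 1] += wp[e] * xc[sp[e] - 1];
  }
  return out;
}

// Three-channel fused message aggregation:
// out[dst[e], ] += sum_b E[pid[e], ch_b] * Xb[src[e], ].
// [[Rcpp::export]]
NumericMatrix edge_scatter3(NumericMatrix X1, NumericMatrix X2, NumericMatrix X3,
                            NumericMatrix E, IntegerVector channels,
                            IntegerVector src, IntegerVector dst,
                            IntegerVector pid, int n_out) {
  const int N = src.size(), h = X1.ncol(), nr = X1.nrow(), ne = E.nrow();
  NumericMatrix out(n_out, h);
  const double* e1 = E.begin() + (size_t)(channels[0] - 1) * ne;
  const double* e2 = E.begin() + (size_t)(channels[1] - 1) * ne;
  const double* e3 = E.begin() + (size_t)(channels[2] - 1) * ne;
  const int* sp = src.begin();
  const int* dp = dst.begin();
  const int* ip = pid.begin();
  for (int c = 0; c < h; ++c) {
    const double* x1 = X1.begin() + (size_t)c * nr;
    const double* x2 = X2.begin() + (size_t)c * nr;
    const double* x3 = X3.begin() + (size_t)c * nr;
    double* oc = out.begin() + (size_t)c * n_out;
    for (int e = 0; e < N; ++e) {
      const int s = sp[e] - 1, d = dp[e] - 1, p = ip[e] - 1;
      oc[d] += e1[p] * x1[s] + e2[p] * x2[s] + e3[p] * x3[s];
    }
  }
  return out;
}

// Backward of edge_scatter3 w.r.t. the three inputs: for each channel b,
// dXb[src[e], ] += E[pid[e], ch_b] * G[dst[e], ]; and w.r.t. E:
// dE[pid[e], ch_b] += sum_c G[dst[e], c] * Xb[src[e], c], folded over the
// two directions by the caller.
// [[Rcpp::export]]
List edge_scatter3_backward(NumericMatrix G, NumericMatrix X1, NumericMatrix X2,
                            NumericMatrix X3, NumericMatrix E,
                            IntegerVector channels, IntegerVector src,
                            IntegerVector dst, IntegerVector pid) {
  const int N = src.size(), h = G.ncol(), nr = X1.nrow(), ng = G.nrow(), ne = E.nrow();
  NumericMatrix d1(nr, h), d2(nr, h), d3(nr, h);
  NumericVector v1(N), v2(N), v3(N);
  const double* e1 = E.begin() + (size_t)(channels[0] - 1) * ne;
  const double* e2 = E.begin() + (size_t)(channels[1] - 1) * ne;
  const double* e3 = E.begin() + (size_t)(channels[2] - 1) * ne;
  const int* sp = src.begin();
  const int* dp = dst.begin();
  const int* ip = pid.begin();
  for (int c = 0; c < h; ++c) {
    const double* gc = G.begin() + (size_t)c * ng;
    const double* x1 = X1.begin() + (size_t)c * nr;
    const double* x2 = X2.begin() + (size_t)c * nr;
    const double* x3 = X3.begin() + (size_t)c * nr;
    double* p1 = d1.begin() + (size_t)c * nr;
    double* p2 = d2.begin() + (size_t)c * nr;
    double* p3 = d3.begin() + (size_t)c * nr;
    for (int e = 0; e < N; ++e) {
      const int s = sp[e] - 1, d = dp[e] - 1, p = ip[e] - 1;
      const double g = gc[d];
      p1[s] += e1[p] * g;
      p2[s] += e2[p] * g;
      p3[s] += e3[p] * g;
      v1[e] += g * x1[s];
      v2[e] += g * x2[s];
      v3[e] += g * x3[s];
    }
  }
  return List::create(_["d1"] = d1, _["d2"] = d2, _["d3"] = d3,
                      _["v1"] = v1, _["v2"] = v2, _["v3"] = v3);
}

// Fused RMSProp update: returns the new parameter and second-moment state in
// one pass (gradient pre-scaled by the clip factor).
// [[Rcpp::export]]
List rmsprop_update(NumericMatrix param, NumericMatrix grad, NumericMatrix state,
                    double lr, double rho, double eps, double scale) {
  const R_xlen_t n = param.size();
  NumericMatrix p2(param.nrow(), param.ncol());
  NumericMatrix v2(param.nrow(), param.ncol());
  const double* pp = param.begin();
  const double* gp = grad.begin();
  const double* vp = state.begin();
  double* p2p = p2.begin();
  double* v2p = v2.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double g = gp[i] * scale;
    const double v = rho * vp[i] + (1.0 - rho) * g * g;
    v2p[i] = v;
    p2p[i] = pp[i] - lr * g / (std::sqrt(v) + eps);
  }
  return List::create(_["param"] = p2, _["state"] = v2);
}

// out[e] = sum_c A[ai[e], c] * B[bi[e], c] (per-edge row dot product).
// [[Rcpp::export]]
NumericVector edge_dot(NumericMatrix A, NumericMatrix B,
                       IntegerVector ai, IntegerVector bi) {
  const int N = ai.size(), h = A.ncol();
  const int nra = A.nrow(), nrb = B.nrow();
  NumericVector out(N);
  const double* ap = A.begin();
  const double* bp = B.begin();
  const int* aip = ai.begin();
  const int* bip = bi.begin();
  double* op = out.begin();
  for (int c = 0; c < h; ++c) {
    const double* ac = ap + (size_t)c * nra;
    const double* bc = bp + (size_t)c * nrb;
    for (int e = 0; e < N; ++e) op[e] += ac[aip[e] - 1] * bc[bip[e] - 1];
  }
  return out;
}
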