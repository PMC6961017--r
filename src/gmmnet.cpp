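#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// GMM-filter graph convolution kernels.
//
// A layer holds, per (output channel m, input channel n) pair, a filter made
// of J Gaussians with weights g, 2-D means (mux, muy) and diagonal
// log-variances (lvx, lvy). Parameter arrays have R dim c(J, N, M), i.e.
// 0-based flat index j + J*n + J*N*m. Edges are directed (s, t) pairs with
// pseudo-coordinates u(s, t); the layer output at node s accumulates, over
// edges leaving s and input channels n, the filter response at u times the
// input feature of t.
//
// Activation codes: 0 identity, 1 ReLU.

namespace {

inline double act_fun(double x, int code) {
  return (code == 1 && x < 0) ? 0.0 : x;
}
inline double act_grad(double pre, int code) {
  return (code == 1 && pre <= 0) ? 0.0 : 1.0;
}

struct Layer {
  int N, M, J, act;
  const double *g, *mux, *muy, *lvx, *lvy, *b;
};

Layer unpack(const List& l) {
  Layer L;
  L.N = as<int>(l["N"]); L.M = as<int>(l["M"]); L.J = as<int>(l["J"]);
  L.act = as<int>(l["act"]);
  L.g   = REAL(as<NumericVector>(l["g"]));
  L.mux = REAL(as<NumericVector>(l["mux"]));
  L.muy = REAL(as<NumericVector>(l["muy"]));
  L.lvx = REAL(as<NumericVector>(l["lvx"]));
  L.lvy = REAL(as<NumericVector>(l["lvy"]));
  L.b   = REAL(as<NumericVector>(l["b"]));
  return L;
}

} // namespace

// Forward pass through all layers. Edges es/et are 0-based, u is E x 2.
// When want_cache is true the per-layer inputs, pre-activations and Gaussian
// evaluations are returned for the backward pass.
// [[Rcpp::export]]
List cpp_net_forward(List layers, IntegerVector es, IntegerVector et,
                     NumericVector ux, NumericVector uy,
                     NumericMatrix f0, bool want_cache) {
  const int E = es.size();
  const int K = f0.nrow();
  const int Lc = layers.size();
  List inputs(Lc), pres(Lc), zcaches(Lc);
  NumericMatrix f = f0;

  for (int li = 0; li < Lc; ++li) {
    Layer L = unpack(as<List>(layers[li]));
    if (f.ncol() != L.N) stop("layer %d expects %d input channels, got %d",
                              li + 1, L.N, (int)f.ncol());
    const int N = L.N, M = L.M, J = L.J;
    // precompute inverse variances
    std::vector<double> ivx(J * N * M), ivy(J * N * M);
    for (int i = 0; i < J * N * M; ++i) {
      ivx[i] = std::exp(-L.lvx[i]);
      ivy[i] = std::exp(-L.lvy[i]);
    }
    // effective bias per output channel: sum of its filters' biases
    NumericMatrix pre(K, M);
    for (int m = 0; m < M; ++m) {
      double bm = 0.0;
      for (int n = 0; n < N; ++n) bm += L.b[n + N * m];
      for (int s = 0; s < K; ++s) pre(s, m) = bm;
    }

    NumericVector zc;
    double* zp = nullptr;
    if (want_cache) {
      zc = NumericVector((R_xlen_t)E * N * M * J);
      zp = REAL(zc);
    }

    const double* fp = REAL(f);
    double* pp = REAL(pre);
    for (int e = 0; e < E; ++e) {
      const int s = es[e], t = et[e];
      const double uxe = ux[e], uye = uy[e];
      for (int m = 0; m < M; ++m) {
        const int base_m = J * N * m;
        double accm = 0.0;
        for (int n = 0; n < N; ++n) {
          const double ft = fp[t + (R_xlen_t)K * n];
          // ft == 0 contributes nothing forward, and with ReLU inputs the
          // gradient through a zero feature is zero as well; skip (the z
          // cache stays zero there and backward skips symmetrically).
          if (ft == 0.0) continue;
          const int base = base_m + J * n;
          double w = 0.0;
          if (zp) {
            double* z_e = zp + (((R_xlen_t)e * N + n) * M + m) * J;
            for (int j = 0; j < J; ++j) {
              const int q = base + j;
              const double dx = uxe - L.mux[q], dy = uye - L.muy[q];
              const double z = std::exp(-0.5 * (dx * dx * ivx[q] + dy * dy * ivy[q]));
              z_e[j] = z;
              w += L.g[q] * z;
            }
          } else {
            for (int j = 0; j < J; ++j) {
              const int q = base + j;
              const double dx = uxe - L.mux[q], dy = uye - L.muy[q];
              w += L.g[q] * std::exp(-0.5 * (dx * dx * ivx[q] + dy * dy * ivy[q]));
            }
          }
          accm += w * ft;
        }
        pp[s + (R_xlen_t)K * m] += accm;
      }
    }

    NumericMatrix h(K, M);
    for (int m = 0; m < M; ++m)
      for (int s = 0; s < K; ++s) h(s, m) = act_fun(pre(s, m), L.act);

    if (want_cache) {
      inputs[li] = f;
      pres[li] = pre;
      zcaches[li] = zc;
    }
    f = h;
  }

  return List::create(_["out"] = f, _["inputs"] = inputs, _["pre"] = pres,
                      _["z"] = zcaches);
}

// Backward pass: given dL/d(out) of the last layer, return per-layer
// parameter gradients. Requires the caches from cpp_net_forward.
// [[Rcpp::export]]
List cpp_net_backward(List layers, IntegerVector es, IntegerVector et,
                      NumericVector ux, NumericVector uy,
                      List inputs, List pres, List zcaches,
                      NumericMatrix dout) {
  const int E = es.size();
  const int Lc = layers.size();
  List grads(Lc);
  NumericMatrix dcur = dout;

  for (int li = Lc - 1; li >= 0; --li) {
    Layer L = unpack(as<List>(layers[li]));
    const int N = L.N, M = L.M, J = L.J;
    NumericMatrix f = as<NumericMatrix>(inputs[li]);
    NumericMatrix pre = as<NumericMatrix>(pres[li]);
    NumericVector zc = as<NumericVector>(zcaches[li]);
    const double* zp = REAL(zc);
    const int K = f.nrow();

    std::vector<double> ivx(J * N * M), ivy(J * N * M);
    for (int i = 0; i < J * N * M; ++i) {
      ivx[i] = std::exp(-L.lvx[i]);
      ivy[i] = std::exp(-L.lvy[i]);
    }

    // gradient through activation; every filter bias of channel m receives
    // the same channel-sum gradient
    NumericMatrix dpre(K, M);
    NumericVector db(N * M);
    for (int m = 0; m < M; ++m) {
      double sb = 0.0;
      for (int s = 0; s < K; ++s) {
        double d = dcur(s, m) * act_grad(pre(s, m), L.act);
        dpre(s, m) = d;
        sb += d;
      }
      for (int n = 0; n < N; ++n) db[n + N * m] = sb;
    }

    NumericVector dg(J * N * M), dmux(J * N * M), dmuy(J * N * M),
                  dlvx(J * N * M), dlvy(J * N * M);
    NumericMatrix df(K, N);
    const double* fp = REAL(f);
    const double* dp = REAL(dpre);
    double* dfp = REAL(df);

    for (int e = 0; e < E; ++e) {
      const int s = es[e], t = et[e];
      const double uxe = ux[e], uye = uy[e];
      for (int m = 0; m < M; ++m) {
        const double delta = dp[s + (R_xlen_t)K * m];
        if (delta == 0.0) continue;
        const int base_m = J * N * m;
        for (int n = 0; n < N; ++n) {
          const double ft = fp[t + (R_xlen_t)K * n];
          if (ft == 0.0) continue;  // mirrors the forward skip
          const int base = base_m + J * n;
          const double* z_e = zp + (((R_xlen_t)e * N + n) * M + m) * J;
          const double c = delta * ft;
          double w = 0.0;
          for (int j = 0; j < J; ++j) {
            const int q = base + j;
            const double z = z_e[j];
            const double gz = L.g[q] * z;
            w += gz;
            const double cc = gz * c;
            const double dx = uxe - L.mux[q], dy = uye - L.muy[q];
            dg[q]   += c * z;
            dmux[q] += cc * dx * ivx[q];
            dmuy[q] += cc * dy * ivy[q];
            dlvx[q] += 0.5 * cc * dx * dx * ivx[q];
            dlvy[q] += 0.5 * cc * dy * dy * ivy[q];
          }
          dfp[t + (R_xlen_t)K * n] += delta * w;
        }
      }
    }

    grads[li] = List::create(_["g"] = dg, _["mux"] = dmux, _["muy"] = dmuy,
                             _["lvx"] = dlvx, _["lvy"] = dlvy, _["b"] = db);
    dcur = df;
  }
  return grads;
}
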