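#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// All kernels below are deliberately plain loops: the arrays involved are
// small (grids up to ~56x56, channel counts in the tens) and plain C++ is
// deterministic across runs, which the training loop relies on.

static inline int idx3(int i, int j, int c, int H, int W) {
  return i + H * (j + W * c);
}

// 2-D convolution, stride `s`, symmetric zero padding `p`.
// x: (H, W, Cin) array; w: (k, k, Cin, Cout); b: length Cout.
// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             int s, int p) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("kernel/input channel mismatch");
  int Ho = (H + 2 * p - k) / s + 1;
  int Wo = (W + 2 * p - k) / s + 1;
  NumericVector y(Ho * Wo * Cout);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  double *yp = y.begin();
  const double *xp = x.begin(), *wp = w.begin();
  for (int co = 0; co < Cout; ++co) {
    double bias = b[co];
    double *yc = yp + (size_t)Ho * Wo * co;
    for (int t = 0; t < Ho * Wo; ++t) yc[t] = bias;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = xp + (size_t)H * W * ci;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          double wv = wp[ki + k * (kj + k * (ci + Cin * co))];
          // valid output ranges so the inner loops are branch-free
          int io0 = std::max(0, (p - ki + s - 1) / s);
          int io1 = std::min(Ho - 1, (H - 1 - ki + p) / s);
          int jo0 = std::max(0, (p - kj + s - 1) / s);
          int jo1 = std::min(Wo - 1, (W - 1 - kj + p) / s);
          for (int jo = jo0; jo <= jo1; ++jo) {
            int j = jo * s - p + kj;
            const double *xcol = xc + (size_t)H * j;
            double *ycol = yc + (size_t)Ho * jo;
            for (int io = io0; io <= io1; ++io)
              ycol[io] += wv * xcol[io * s - p + ki];
          }
        }
      }
    }
  }
  return y;
}

// Reverse-mode gradients of conv2d_fwd_cpp w.r.t. input, weights and bias.
// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector gy, NumericVector x, NumericVector w,
                    int s, int p) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = gy.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int k = wd[0], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  NumericVector gx(x.size()), gw(w.size());
  NumericVector gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const double *xp = x.begin(), *wp = w.begin(), *gyp = gy.begin();
  double *gxp = gx.begin(), *gwp = gw.begin();
  for (int co = 0; co < Cout; ++co) {
    const double *gyc = gyp + (size_t)Ho * Wo * co;
    double acc_b = 0;
    for (int t = 0; t < Ho * Wo; ++t) acc_b += gyc[t];
    gb[co] += acc_b;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = xp + (size_t)H * W * ci;
      double *gxc = gxp + (size_t)H * W * ci;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          int wi = ki + k * (kj + k * (ci + Cin * co));
          double wv = wp[wi], acc_w = 0;
          int io0 = std::max(0, (p - ki + s - 1) / s);
          int io1 = std::min(Ho - 1, (H - 1 - ki + p) / s);
          int jo0 = std::max(0, (p - kj + s - 1) / s);
          int jo1 = std::min(Wo - 1, (W - 1 - kj + p) / s);
          for (int jo = jo0; jo <= jo1; ++jo) {
            int j = jo * s - p + kj;
            const double *xcol = xc + (size_t)H * j;
            double *gxcol = gxc + (size_t)H * j;
            const double *gycol = gyc + (size_t)Ho * jo;
            for (int io = io0; io <= io1; ++io) {
              double g = gycol[io];
              int i = io * s - p + ki;
              gxcol[i] += g * wv;
              acc_w += g * xcol[i];
            }
          }
          gwp[wi] += acc_w;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

struct DSU {
  std::vector<int> parent;
  DSU(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int v) {
    while (parent[v] != v) { parent[v] = parent[parent[v]]; v = parent[v]; }
    return v;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[b] = a;
    return true;
  }
};

// Boruvka minimum spanning tree on an undirected edge list (0-based vertex
// ids).  Ties in edge weight are broken by the smaller edge index, so the
// effective weights are a strict total order and the result is deterministic.
// Returns 0-based indices of the V-1 selected edges.
// [[Rcpp::export]]
IntegerVector boruvka_mst_cpp(IntegerVector eu, IntegerVector ev,
                              NumericVector dist, int nv) {
  int ne = eu.size();
  if (nv == 1) return IntegerVector(0);
  DSU dsu(nv);
  std::vector<int> chosen;
  chosen.reserve(nv - 1);
  int ncomp = nv;
  while (ncomp > 1) {
    // cheapest outgoing edge per component, by (dist, index)
    std::vector<int> best(nv, -1);
    for (int e = 0; e < ne; ++e) {
      int ru = dsu.find(eu[e]), rv = dsu.find(ev[e]);
      if (ru == rv) continue;
      for (int r : {ru, rv}) {
        if (best[r] < 0 || dist[e] < dist[best[r]] ||
            (dist[e] == dist[best[r]] && e < best[r])) {
          best[r] = e;
        }
      }
    }
    bool merged = false;
    for (int r = 0; r < nv; ++r) {
      int e = best[r];
      if (e < 0 || dsu.find(r) != r) continue;
      if (dsu.unite(eu[e], ev[e])) {
        chosen.push_back(e);
        --ncomp;
        merged = true;
      }
    }
    if (!merged) stop("graph not connected");
  }
  std::sort(chosen.begin(), chosen.end());
  return wrap(chosen);
}

// Breadth-first traversal of a spanning tree given by its edge list.
// Children are visited in ascending vertex id.  Returns the visitation
// order and the parent array (-1 at the root); errors if the edges do not
// form a tree spanning all nv vertices.
// [[Rcpp::export]]
List bfs_tree_cpp(IntegerVector eu, IntegerVector ev, int nv, int root) {
  int ne = eu.size();
  if (ne != nv - 1) stop("edges do not form a spanning tree");
  std::vector<std::vector<int>> adj(nv);
  for (int e = 0; e < ne; ++e) {
    adj[eu[e]].push_back(ev[e]);
    adj[ev[e]].push_back(eu[e]);
  }
  for (int v = 0; v < nv; ++v) std::sort(adj[v].begin(), adj[v].end());
  IntegerVector order(nv), parent(nv, -1);
  std::vector<char> seen(nv, 0);
  std::vector<int> queue;
  queue.reserve(nv);
  queue.push_back(root);
  seen[root] = 1;
  for (int head = 0; head < (int)queue.size(); ++head) {
    int v = queue[head];
    order[head] = v;
    for (int u : adj[v]) {
      if (!seen[u]) {
        seen[u] = 1;
        parent[u] = v;
        queue.push_back(u);
      }
    }
  }
  if ((int)queue.size() != nv) stop("edges do not form a spanning tree");
  return List::create(_["order"] = order, _["parent"] = parent);
}

// exact GELU x * Phi(x) and its derivative Phi(x) + x * phi(x)
// [[Rcpp::export]]
NumericMatrix gelu_fwd_mat_cpp(NumericMatrix x) {
  NumericMatrix y(x.nrow(), x.ncol());
  int n = x.size();
  for (int t = 0; t < n; ++t) {
    double v = x[t];
    y[t] = 0.5 * v * (1.0 + std::erf(v * M_SQRT1_2));
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix gelu_bwd_mat_cpp(NumericMatrix gy, NumericMatrix x) {
  NumericMatrix gx(x.nrow(), x.ncol());
  int n = x.size();
  const double inv_sqrt_2pi = 0.3989422804014327;
  for (int t = 0; t < n; ++t) {
    double v = x[t];
    double Phi = 0.5 * (1.0 + std::erf(v * M_SQRT1_2));
    double phi = inv_sqrt_2pi * std::exp(-0.5 * v * v);
    gx[t] = gy[t] * (Phi + v * phi);
  }
  return gx;
}

// Row-wise LayerNorm over all columns with affine parameters.
// [[Rcpp::export]]
List ln_fwd_cpp(NumericMatrix x, NumericVector g, NumericVector b, double eps) {
  int V = x.nrow(), K = x.ncol();
  NumericMatrix y(V, K), xhat(V, K);
  NumericVector inv_sd(V);
  for (int v = 0; v < V; ++v) {
    double mu = 0;
    for (int k = 0; k < K; ++k) mu += x(v, k);
    mu /= K;
    double var = 0;
    for (int k = 0; k < K; ++k) { double d = x(v, k) - mu; var += d * d; }
    double r = 1.0 / std::sqrt(var / K + eps);
    inv_sd[v] = r;
    for (int k = 0; k < K; ++k) {
      double xh = (x(v, k) - mu) * r;
      xhat(v, k) = xh;
      y(v, k) = xh * g[k] + b[k];
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv_sd"] = inv_sd);
}

// [[Rcpp::export]]
List ln_bwd_cpp(NumericMatrix gy, NumericMatrix xhat, NumericVector inv_sd,
                NumericVector g) {
  int V = gy.nrow(), K = gy.ncol();
  NumericMatrix gx(V, K);
  NumericVector gg(K), gb(K);
  for (int v = 0; v < V; ++v) {
    double s1 = 0, s2 = 0;
    for (int k = 0; k < K; ++k) {
      double gyh = gy(v, k) * g[k];
      s1 += gyh;
      s2 += gyh * xhat(v, k);
      gg[k] += gy(v, k) * xhat(v, k);
      gb[k] += gy(v, k);
    }
    double r = inv_sd[v] / K;
    for (int k = 0; k < K; ++k) {
      double gyh = gy(v, k) * g[k];
      gx(v, k) = r * (K * gyh - s1 - xhat(v, k) * s2);
    }
  }
  return List::create(_["gx"] = gx, _["gg"] = gg, _["gb"] = gb);
}

// TreeSSM source term: m[v, (f-1)N+n] = u[v, f] * B[n]   (state index fastest)
// [[Rcpp::export]]
NumericMatrix source_fwd_cpp(NumericMatrix u, NumericVector B) {
  int V = u.nrow(), F = u.ncol(), N = B.size();
  NumericMatrix m(V, N * F);
  for (int f = 0; f < F; ++f)
    for (int n = 0; n < N; ++n) {
      int col = f * N + n;
      double b = B[n];
      for (int v = 0; v < V; ++v) m(v, col) = u(v, f) * b;
    }
  return m;
}

// [[Rcpp::export]]
List source_bwd_cpp(NumericMatrix gm, NumericMatrix u, NumericVector B) {
  int V = u.nrow(), F = u.ncol(), N = B.size();
  NumericMatrix gu(V, F);
  NumericVector gB(N);
  for (int f = 0; f < F; ++f)
    for (int n = 0; n < N; ++n) {
      int col = f * N + n;
      double b = B[n], acc = 0;
      for (int v = 0; v < V; ++v) {
        gu(v, f) += gm(v, col) * b;
        acc += gm(v, col) * u(v, f);
      }
      gB[n] += acc;
    }
  return List::create(_["gu"] = gu, _["gB"] = gB);
}

// Output contraction over states: y[v, f] = sum_n C[n] * hn[v, (f-1)N+n]
// [[Rcpp::export]]
NumericMatrix contract_fwd_cpp(NumericMatrix hn, NumericVector C, int F) {
  int V = hn.nrow(), N = C.size();
  NumericMatrix y(V, F);
  for (int f = 0; f < F; ++f)
    for (int n = 0; n < N; ++n) {
      int col = f * N + n;
      double c = C[n];
      for (int v = 0; v < V; ++v) y(v, f) += c * hn(v, col);
    }
  return y;
}

// [[Rcpp::export]]
List contract_bwd_cpp(NumericMatrix gy, NumericMatrix hn, NumericVector C) {
  int V = gy.nrow(), F = gy.ncol(), N = C.size();
  NumericMatrix ghn(V, N * F);
  NumericVector gC(N);
  for (int f = 0; f < F; ++f)
    for (int n = 0; n < N; ++n) {
      int col = f * N + n;
      double c = C[n], acc = 0;
      for (int v = 0; v < V; ++v) {
        ghn(v, col) = gy(v, f) * c;
        acc += gy(v, f) * hn(v, col);
      }
      gC[n] += acc;
    }
  return List::create(_["ghn"] = ghn, _["gC"] = gC);
}

// column scaling: x * v per column
// [[Rcpp::export]]
NumericMatrix scale_cols_cpp(NumericMatrix x, NumericVector v) {
  int V = x.nrow(), K = x.ncol();
  NumericMatrix y(V, K);
  for (int k = 0; k < K; ++k) {
    double s = v[k];
    for (int r = 0; r < V; ++r) y(r, k) = x(r, k) * s;
  }
  return y;
}

// column bias: x + v per column (in a fresh matrix)
// [[Rcpp::export]]
NumericMatrix add_cols_cpp(NumericMatrix x, NumericVector v) {
  int V = x.nrow(), K = x.ncol();
  NumericMatrix y(V, K);
  for (int k = 0; k < K; ++k) {
    double s = v[k];
    for (int r = 0; r < V; ++r) y(r, k) = x(r, k) + s;
  }
  return y;
}

// (H, W, C) array -> (H*W) x C matrix with row-major vertex order
// [[Rcpp::export]]
NumericMatrix arr2mat_cpp(NumericVector arr) {
  IntegerVector d = arr.attr("dim");
  int H = d[0], W = d[1], C = d[2];
  NumericMatrix m(H * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        m(i * W + j, c) = arr[i + H * (j + W * c)];
  return m;
}

// inverse of arr2mat_cpp
// [[Rcpp::export]]
NumericVector mat2arr_cpp(NumericMatrix m, int H, int W) {
  int C = m.ncol();
  NumericVector arr(H * W * C);
  arr.attr("dim") = IntegerVector::create(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        arr[i + H * (j + W * c)] = m(i * W + j, c);
  return arr;
}

// Two-pass (rerooting) tree scan.  m is V x K; wpar[v] is the weight of the
// edge from v to its parent (ignored at the root).  Computes
//   h[i, ] = sum_j (prod of edge weights on tree path i..j) * m[j, ]
// in O(V K): an upward subtree accumulation followed by a downward pass.
// [[Rcpp::export]]
NumericMatrix tree_scan_cpp(NumericMatrix m, IntegerVector order,
                            IntegerVector parent, NumericVector wpar) {
  int V = m.nrow(), K = m.ncol();
  NumericMatrix S(clone(m)), h(V, K);
  // upward: S[v] = m[v] + sum_children w(c) * S[c]
  for (int i = V - 1; i >= 1; --i) {
    int v = order[i], p = parent[v];
    double w = wpar[v];
    for (int k = 0; k < K; ++k) S(p, k) += w * S(v, k);
  }
  int root = order[0];
  for (int k = 0; k < K; ++k) h(root, k) = S(root, k);
  // downward: h[v] = S[v] + w(v) * (h[parent] - w(v) * S[v])
  for (int i = 1; i < V; ++i) {
    int v = order[i], p = parent[v];
    double w = wpar[v];
    for (int k = 0; k < K; ++k) h(v, k) = S(v, k) + w * (h(p, k) - w * S(v, k));
  }
  return h;
}
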