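// Weighted graph metrics on dense adjacency (weight) matrices.
//
// Networks here are small (tens of nodes) but metrics are evaluated on
// millions of degree-preserving null networks, so the per-network cost
// matters far more than asymptotics: dense flat matrices, Floyd-Warshall
// for null path lengths, and a fast counter-based PRNG seeded from R's
// RNG stream (so set.seed() still governs every null) for the rewiring.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// tie tolerance for equal-length shortest paths
static const double EPS = 1e-10;
static const double INF = std::numeric_limits<double>::infinity();

// ---- xoshiro256++ seeded from R's RNG ------------------------------------
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double runif() { return (next() >> 11) * 0x1.0p-53; }
  int below(int n) { return int(runif() * n) % n; }
};

static Xoshiro rng_from_R() {
  // one draw from R's stream -> reproducible under set.seed()
  double u = unif_rand();
  return Xoshiro(uint64_t(u * 9007199254740992.0) + 1ULL);
}

// ---- Onnela weighted clustering ------------------------------------------
// c_i = (2 / (k_i (k_i - 1))) * sum_{j<h in N(i)} (w'_ij w'_ih w'_jh)^(1/3)
// with w' = w / max(w) over the whole network; degree < 2 contributes 0.
static void onnela_clustering(const std::vector<double>& W, int n,
                              std::vector<double>& cc) {
  double wmax = 0.0;
  for (int i = 0; i < n * n; ++i) if (W[i] > wmax) wmax = W[i];
  std::fill(cc.begin(), cc.end(), 0.0);
  if (wmax <= 0.0) return;
  std::vector<double> H(n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (W[i * n + j] > 0.0)
        H[i * n + j] = H[j * n + i] = std::cbrt(W[i * n + j] / wmax);
  std::vector<int> nb(n);
  for (int i = 0; i < n; ++i) {
    int k = 0;
    for (int j = 0; j < n; ++j)
      if (j != i && W[i * n + j] > 0.0) nb[k++] = j;
    if (k < 2) continue;
    double s = 0.0;
    for (int a = 0; a < k; ++a) {
      double hia = H[i * n + nb[a]];
      for (int b = a + 1; b < k; ++b)
        s += hia * H[i * n + nb[b]] * H[nb[a] * n + nb[b]];
    }
    cc[i] = 2.0 * s / (double(k) * double(k - 1));
  }
}

static double mean_clustering(const std::vector<double>& W, int n) {
  std::vector<double> cc(n);
  onnela_clustering(W, n, cc);
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += cc[i];
  return s / double(n);
}

// ---- shortest paths ------------------------------------------------------
// Dijkstra on distances 1/w (O(n^2), no heap); for exported per-network use
static void dijkstra(const std::vector<double>& W, int n, int src,
                     std::vector<double>& dist) {
  std::vector<bool> done(n, false);
  std::fill(dist.begin(), dist.end(), INF);
  dist[src] = 0.0;
  for (int it = 0; it < n; ++it) {
    int u = -1; double best = INF;
    for (int v = 0; v < n; ++v)
      if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
    if (u < 0) break;
    done[u] = true;
    for (int v = 0; v < n; ++v) {
      double w = W[u * n + v];
      if (v == u || w <= 0.0 || done[v]) continue;
      double nd = dist[u] + 1.0 / w;
      if (nd < dist[v]) dist[v] = nd;
    }
  }
}

// mean shortest-path distance over unordered pairs via Floyd-Warshall on
// a reusable scratch buffer; Inf when disconnected
static double char_path_length_fw(const std::vector<double>& W, int n,
                                  std::vector<double>& D) {
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double w = W[i * n + j];
      D[i * n + j] = (i == j) ? 0.0 : (w > 0.0 ? 1.0 / w : INF);
    }
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < n; ++i) {
      double dik = D[i * n + k];
      if (dik == INF) continue;
      const double* Dk = &D[k * n];
      double* Di = &D[i * n];
      for (int j = 0; j < n; ++j) {
        double nd = dik + Dk[j];
        if (nd < Di[j]) Di[j] = nd;
      }
    }
  double tot = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (D[i * n + j] == INF) return INF;
      tot += D[i * n + j];
    }
  return tot / (double(n) * double(n - 1) / 2.0);
}

static std::vector<double> mat_to_vec(const NumericMatrix& M) {
  int n = M.nrow();
  std::vector<double> W(n * n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      W[i * n + j] = M(i, j); // symmetric input, layout moot
  return W;
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_clustering(const NumericMatrix& W) {
  int n = W.nrow();
  std::vector<double> Wv = mat_to_vec(W), cc(n);
  onnela_clustering(Wv, n, cc);
  return wrap(cc);
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_distances(const NumericMatrix& W) {
  int n = W.nrow();
  std::vector<double> Wv = mat_to_vec(W), dist(n);
  NumericMatrix D(n, n);
  for (int s = 0; s < n; ++s) {
    dijkstra(Wv, n, s, dist);
    for (int t = 0; t < n; ++t) D(s, t) = dist[t];
  }
  return D;
}

// ---- Brandes betweenness with edge distance 1/w --------------------------
// Accumulated over ordered source-target pairs, halved to the
// unordered-pair scale. Ties between equally short paths detected with EPS.
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_betweenness(const NumericMatrix& Wm) {
  int n = Wm.nrow();
  std::vector<double> W = mat_to_vec(Wm);
  std::vector<double> bc(n, 0.0), dist(n), sigma(n), delta(n);
  std::vector<bool> done(n);
  std::vector<int> order; order.reserve(n);
  std::vector<std::vector<int> > pred(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    std::fill(done.begin(), done.end(), false);
    for (int v = 0; v < n; ++v) pred[v].clear();
    order.clear();
    dist[s] = 0.0; sigma[s] = 1.0;
    for (int it = 0; it < n; ++it) {
      int u = -1; double best = INF;
      for (int v = 0; v < n; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = true;
      order.push_back(u);
      for (int v = 0; v < n; ++v) {
        double w = W[u * n + v];
        if (v == u || w <= 0.0 || done[v]) continue;
        double nd = dist[u] + 1.0 / w;
        if (nd < dist[v] - EPS) {
          dist[v] = nd;
          sigma[v] = sigma[u];
          pred[v].clear();
          pred[v].push_back(u);
        } else if (std::fabs(nd - dist[v]) <= EPS) {
          sigma[v] += sigma[u];
          pred[v].push_back(u);
        }
      }
    }
    for (int i = int(order.size()) - 1; i >= 0; --i) {
      int wv = order[i];
      for (size_t k = 0; k < pred[wv].size(); ++k) {
        int u = pred[wv][k];
        delta[u] += sigma[u] / sigma[wv] * (1.0 + delta[wv]);
      }
      if (wv != s) bc[wv] += delta[wv];
    }
  }
  NumericVector out(n);
  for (int v = 0; v < n; ++v) out[v] = bc[v] / 2.0;
  return out;
}

// ---- Maslov-Sneppen degree-preserving rewiring ---------------------------
// Double-edge swaps (a,b),(c,d) -> (a,d),(c,b); weights travel with the
// edge of their first endpoint.
struct EdgeList {
  std::vector<int> a, b;
};

static EdgeList edges_of(const std::vector<double>& W, int n) {
  EdgeList e;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (W[i * n + j] > 0.0) { e.a.push_back(i); e.b.push_back(j); }
  return e;
}

// rewires W in place; returns number of failed swap attempts
static int rewire_inplace(std::vector<double>& W, int n, EdgeList& e,
                          int n_swaps, Xoshiro& rng) {
  int m = int(e.a.size());
  int failed = 0;
  if (m < 2) return n_swaps;
  for (int s = 0; s < n_swaps; ++s) {
    int i1 = rng.below(m);
    int i2 = rng.below(m);
    if (i1 == i2) { ++failed; continue; }
    int a = e.a[i1], b = e.b[i1], c = e.a[i2], d = e.b[i2];
    if (rng.runif() < 0.5) std::swap(c, d); // random orientation
    if (a == c || a == d || b == c || b == d) { ++failed; continue; }
    if (W[a * n + d] > 0.0 || W[c * n + b] > 0.0) { ++failed; continue; }
    double w1 = W[a * n + b], w2 = W[c * n + d];
    W[a * n + b] = W[b * n + a] = 0.0;
    W[c * n + d] = W[d * n + c] = 0.0;
    W[a * n + d] = W[d * n + a] = w1;
    W[c * n + b] = W[b * n + c] = w2;
    e.a[i1] = a; e.b[i1] = d;
    e.a[i2] = c; e.b[i2] = b;
  }
  return failed;
}

static bool is_connected(const std::vector<double>& W, int n) {
  std::vector<int> stack(1, 0);
  std::vector<bool> seen(n, false);
  seen[0] = true;
  int cnt = 1;
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    for (int v = 0; v < n; ++v)
      if (!seen[v] && W[u * n + v] > 0.0) {
        seen[v] = true; ++cnt; stack.push_back(v);
      }
  }
  return cnt == n;
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_rewire(const NumericMatrix& Wm, int n_swaps) {
  int n = Wm.nrow();
  std::vector<double> W = mat_to_vec(Wm);
  EdgeList e = edges_of(W, n);
  Xoshiro rng = rng_from_R();
  int failed = rewire_inplace(W, n, e, n_swaps, rng);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) out(i, j) = W[i * n + j];
  out.attr("failed_swaps") = failed;
  return out;
}

// ---- null-ensemble engine ------------------------------------------------
// Rewiring only permutes edge placements, so the per-edge transforms
// needed by the metrics — cbrt(w/wmax) for clustering and 1/w for path
// length — are computed once on the real network and travel with the
// edges through the swaps.
struct NullEngine {
  int n;
  std::vector<double> H0, D0;     // clustering weights; direct distances
  std::vector<int> a0, b0;        // edge endpoints
  std::vector<double> H, D;       // per-null scratch
  std::vector<int> a, b;
  std::vector<double> cc;
  std::vector<bool> seen;
  std::vector<int> stack, nb;

  explicit NullEngine(const std::vector<double>& W, int n_) : n(n_) {
    double wmax = 0.0;
    for (int i = 0; i < n * n; ++i) if (W[i] > wmax) wmax = W[i];
    H0.assign(n * n, 0.0);
    D0.assign(n * n, INF);
    for (int i = 0; i < n; ++i) D0[i * n + i] = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (W[i * n + j] > 0.0) {
          a0.push_back(i); b0.push_back(j);
          double h = std::cbrt(W[i * n + j] / wmax);
          double d = 1.0 / W[i * n + j];
          H0[i * n + j] = H0[j * n + i] = h;
          D0[i * n + j] = D0[j * n + i] = d;
        }
    cc.resize(n); seen.resize(n); nb.resize(n);
  }

  // swap on H and D simultaneously; presence test via H > 0
  int rewire(int n_swaps, Xoshiro& rng) {
    int m = int(a.size()), failed = 0;
    if (m < 2) return n_swaps;
    for (int s = 0; s < n_swaps; ++s) {
      int i1 = rng.below(m), i2 = rng.below(m);
      if (i1 == i2) { ++failed; continue; }
      int A = a[i1], B = b[i1], C = a[i2], Dd = b[i2];
      if (rng.runif() < 0.5) std::swap(C, Dd);
      if (A == C || A == Dd || B == C || B == Dd) { ++failed; continue; }
      if (H[A * n + Dd] > 0.0 || H[C * n + B] > 0.0) { ++failed; continue; }
      double h1 = H[A * n + B], h2 = H[C * n + Dd];
      double d1 = D[A * n + B], d2 = D[C * n + Dd];
      H[A * n + B] = H[B * n + A] = 0.0; D[A * n + B] = D[B * n + A] = INF;
      H[C * n + Dd] = H[Dd * n + C] = 0.0; D[C * n + Dd] = D[Dd * n + C] = INF;
      H[A * n + Dd] = H[Dd * n + A] = h1; D[A * n + Dd] = D[Dd * n + A] = d1;
      H[C * n + B] = H[B * n + C] = h2; D[C * n + B] = D[B * n + C] = d2;
      a[i1] = A; b[i1] = Dd;
      a[i2] = C; b[i2] = B;
    }
    return failed;
  }

  bool connected() {
    std::fill(seen.begin(), seen.end(), false);
    stack.clear(); stack.push_back(0); seen[0] = true;
    int cnt = 1;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (int v = 0; v < n; ++v)
        if (!seen[v] && H[u * n + v] > 0.0) {
          seen[v] = true; ++cnt; stack.push_back(v);
        }
    }
    return cnt == n;
  }

  double clustering() {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      int k = 0;
      for (int j = 0; j < n; ++j)
        if (j != i && H[i * n + j] > 0.0) nb[k++] = j;
      if (k < 2) continue;
      double s = 0.0;
      for (int p = 0; p < k; ++p) {
        double hip = H[i * n + nb[p]];
        for (int q = p + 1; q < k; ++q)
          s += hip * H[i * n + nb[q]] * H[nb[p] * n + nb[q]];
      }
      tot += 2.0 * s / (double(k) * double(k - 1));
    }
    return tot / double(n);
  }

  // Floyd-Warshall in place on D (already a per-null copy)
  double path_length() {
    for (int k = 0; k < n; ++k)
      for (int i = 0; i < n; ++i) {
        double dik = D[i * n + k];
        if (dik == INF) continue;
        const double* Dk = &D[k * n];
        double* Di = &D[i * n];
        for (int j = 0; j < n; ++j)
          Di[j] = std::min(Di[j], dik + Dk[j]);
      }
    double tot = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        tot += D[i * n + j];
    return tot / (double(n) * double(n - 1) / 2.0);
  }

  // one connected null's (cp, lp); throws after max_tries failures
  void draw_null(int n_swaps, int max_tries, Xoshiro& rng,
                 double& cp, double& lp) {
    bool ok = false;
    for (int t = 0; t < max_tries && !ok; ++t) {
      H = H0; D = D0; a = a0; b = b0;
      rewire(n_swaps, rng);
      ok = connected();
    }
    if (!ok)
      stop("could not generate a connected null network in %d tries",
           max_tries);
    cp = clustering();
    lp = path_length();
  }
};

// Null networks for normalization are drawn connected (rejection
// sampling), matching the real networks' construction guarantee; a
// disconnected null has infinite path length and no comparable Lp.
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_null_global(const NumericMatrix& Wm, int n_nulls,
                              int n_swaps, int max_tries = 100) {
  int n = Wm.nrow();
  std::vector<double> W0 = mat_to_vec(Wm);
  NullEngine eng(W0, n);
  Xoshiro rng = rng_from_R();
  NumericMatrix out(n_nulls, 2);
  for (int r = 0; r < n_nulls; ++r) {
    double cp, lp;
    eng.draw_null(n_swaps, max_tries, rng, cp, lp);
    out(r, 0) = cp;
    out(r, 1) = lp;
  }
  return out;
}

// Per-subject global profile over a sparsity sweep in one call:
// for each network, the real Cp and Lp plus null-ensemble means.
// Returns length(Ws) x 4: cp, lp, mean_null_cp, mean_null_lp.
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_global_profile(List Ws, int n_nulls, int swap_mult,
                                 int max_tries = 100) {
  int nlev = Ws.size();
  NumericMatrix out(nlev, 4);
  Xoshiro rng = rng_from_R();
  for (int l = 0; l < nlev; ++l) {
    NumericMatrix Wm = Ws[l];
    int n = Wm.nrow();
    std::vector<double> W = mat_to_vec(Wm), D(n * n);
    out(l, 0) = mean_clustering(W, n);
    out(l, 1) = char_path_length_fw(W, n, D);
    NullEngine eng(W, n);
    int n_swaps = swap_mult * int(eng.a0.size());
    double scp = 0.0, slp = 0.0;
    for (int r = 0; r < n_nulls; ++r) {
      double cp, lp;
      eng.draw_null(n_swaps, max_tries, rng, cp, lp);
      scp += cp; slp += lp;
    }
    out(l, 2) = scp / n_nulls;
    out(l, 3) = slp / n_nulls;
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_global_metrics(const NumericMatrix& Wm) {
  int n = Wm.nrow();
  std::vector<double> W = mat_to_vec(Wm), D(n * n);
  NumericVector out = NumericVector::create(
    _["cp"] = mean_clustering(W, n),
    _["lp"] = char_path_length_fw(W, n, D));
  return out;
}
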