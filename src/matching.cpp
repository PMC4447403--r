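// Exact minimum-weight perfect matching on a complete graph, via the
// primal-dual blossom algorithm for maximum weight matching (O(n^3)).
// Distances are mapped to integer weights w = round((1 - d/dmax) * SCALE) + 1;
// all weights positive, so the maximum weight matching on a complete graph
// with an even number of vertices is perfect, and maximizing the transformed
// weight minimizes the original distance sum.

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <algorithm>
#include <cstdint>

namespace {

typedef long long ll;
const ll INFLL = (ll)1e18;

struct Edge {
  int u, v;
  ll w;
};

struct Blossom {
  int n, n_x;
  std::vector<std::vector<Edge> > g;
  std::vector<ll> lab;
  std::vector<int> match_, slack_, st, pa, S, vis;
  std::vector<std::vector<int> > flower, flower_from;
  std::deque<int> q;
  int t_lca;

  explicit Blossom(int n_) : n(n_), n_x(n_), t_lca(0) {
    int m = n * 2 + 2;
    g.assign(m, std::vector<Edge>(m));
    for (int u = 0; u < m; ++u)
      for (int v = 0; v < m; ++v) {
        g[u][v].u = u; g[u][v].v = v; g[u][v].w = 0;
      }
    lab.assign(m, 0);
    match_.assign(m, 0); slack_.assign(m, 0); st.assign(m, 0);
    pa.assign(m, 0); S.assign(m, 0); vis.assign(m, 0);
    flower.assign(m, std::vector<int>());
    flower_from.assign(m, std::vector<int>(n + 1, 0));
  }

  ll e_delta(const Edge &e) const {
    return lab[e.u] + lab[e.v] - g[e.u][e.v].w * 2;
  }

  void update_slack(int u, int x) {
    if (!slack_[x] || e_delta(g[u][x]) < e_delta(g[slack_[x]][x]))
      slack_[x] = u;
  }

  void set_slack(int x) {
    slack_[x] = 0;
    for (int u = 1; u <= n; ++u)
      if (g[u][x].w > 0 && st[u] != x && S[st[u]] == 0) update_slack(u, x);
  }

  void q_push(int x) {
    if (x <= n) { q.push_back(x); return; }
    for (size_t i = 0; i < flower[x].size(); ++i) q_push(flower[x][i]);
  }

  void set_st(int x, int b) {
    st[x] = b;
    if (x > n)
      for (size_t i = 0; i < flower[x].size(); ++i) set_st(flower[x][i], b);
  }

  int get_pr(int b, int xr) {
    int pr = (int)(std::find(flower[b].begin(), flower[b].end(), xr) -
                   flower[b].begin());
    if (pr % 2 == 1) {
      std::reverse(flower[b].begin() + 1, flower[b].end());
      return (int)flower[b].size() - pr;
    }
    return pr;
  }

  void set_match(int u, int v) {
    match_[u] = g[u][v].v;
    if (u <= n) return;
    Edge &e = g[u][v];
    int xr = flower_from[u][e.u], pr = get_pr(u, xr);
    for (int i = 0; i < pr; ++i)
      set_match(flower[u][i], flower[u][i ^ 1]);
    set_match(xr, v);
    std::rotate(flower[u].begin(), flower[u].begin() + pr, flower[u].end());
  }

  void augment(int u, int v) {
    for (;;) {
      int xnv = st[match_[u]];
      set_match(u, v);
      if (!xnv) return;
      set_match(xnv, st[pa[xnv]]);
      u = st[pa[xnv]]; v = xnv;
    }
  }

  int get_lca(int u, int v) {
    for (++t_lca; u || v; std::swap(u, v)) {
      if (u == 0) continue;
      if (vis[u] == t_lca) return u;
      vis[u] = t_lca;
      u = st[match_[u]];
      if (u) u = st[pa[u]];
    }
    return 0;
  }

  void add_blossom(int u, int lca, int v) {
    int b = n + 1;
    while (b <= n_x && st[b]) ++b;
    if (b > n_x) ++n_x;
    lab[b] = 0; S[b] = 0;
    match_[b] = match_[lca];
    flower[b].clear();
    flower[b].push_back(lca);
    for (int x = u, y; x != lca; x = st[pa[y]]) {
      flower[b].push_back(x);
      flower[b].push_back(y = st[match_[x]]);
      q_push(y);
    }
    std::reverse(flower[b].begin() + 1, flower[b].end());
    for (int x = v, y; x != lca; x = st[pa[y]]) {
      flower[b].push_back(x);
      flower[b].push_back(y = st[match_[x]]);
      q_push(y);
    }
    set_st(b, b);
    for (int x = 1; x <= n_x; ++x) g[b][x].w = g[x][b].w = 0;
    for (int x = 1; x <= n; ++x) flower_from[b][x] = 0;
    for (size_t i = 0; i < flower[b].size(); ++i) {
      int xs = flower[b][i];
      for (int x = 1; x <= n_x; ++x)
        if (g[b][x].w == 0 || e_delta(g[xs][x]) < e_delta(g[b][x])) {
          g[b][x] = g[xs][x];
          g[x][b] = g[x][xs];
        }
      for (int x = 1; x <= n; ++x)
        if (flower_from[xs][x]) flower_from[b][x] = xs;
    }
    set_slack(b);
  }

  void expand_blossom(int b) {
    for (size_t i = 0; i < flower[b].size(); ++i)
      set_st(flower[b][i], flower[b][i]);
    int xr = flower_from[b][g[b][pa[b]].u], pr = get_pr(b, xr);
    for (int i = 0; i < pr; i += 2) {
      int xs = flower[b][i], xns = flower[b][i + 1];
      pa[xs] = g[xns][xs].u;
      S[xs] = 1; S[xns] = 0;
      slack_[xs] = 0; set_slack(xns);
      q_push(xns);
    }
    S[xr] = 1; pa[xr] = pa[b];
    for (int i = pr + 1; i < (int)flower[b].size(); ++i) {
      int xs = flower[b][i];
      S[xs] = -1;
      set_slack(xs);
    }
    st[b] = 0;
  }

  bool on_found_edge(const Edge &e) {
    int u = st[e.u], v = st[e.v];
    if (S[v] == -1) {
      pa[v] = e.u; S[v] = 1;
      int nu = st[match_[v]];
      slack_[v] = slack_[nu] = 0;
      S[nu] = 0; q_push(nu);
    } else if (S[v] == 0) {
      int lca = get_lca(u, v);
      if (!lca) {
        augment(u, v); augment(v, u);
        return true;
      }
      add_blossom(u, lca, v);
    }
    return false;
  }

  bool matching_round() {
    std::fill(S.begin(), S.begin() + n_x + 1, -1);
    std::fill(slack_.begin(), slack_.begin() + n_x + 1, 0);
    q.clear();
    for (int x = 1; x <= n_x; ++x)
      if (st[x] == x && !match_[x]) { pa[x] = 0; S[x] = 0; q_push(x); }
    if (q.empty()) return false;
    for (;;) {
      while (!q.empty()) {
        int u = q.front(); q.pop_front();
        if (S[st[u]] == 1) continue;
        for (int v = 1; v <= n; ++v)
          if (g[u][v].w > 0 && st[u] != st[v]) {
            if (e_delta(g[u][v]) == 0) {
              if (on_found_edge(g[u][v])) return true;
            } else {
              update_slack(u, st[v]);
            }
          }
      }
      ll d = INFLL;
      for (int b = n + 1; b <= n_x; ++b)
        if (st[b] == b && S[b] == 1) d = std::min(d, lab[b] / 2);
      for (int x = 1; x <= n_x; ++x)
        if (st[x] == x && slack_[x]) {
          if (S[x] == -1)
            d = std::min(d, e_delta(g[slack_[x]][x]));
          else if (S[x] == 0)
            d = std::min(d, e_delta(g[slack_[x]][x]) / 2);
        }
      for (int u = 1; u <= n; ++u) {
        if (S[st[u]] == 0) {
          if (lab[u] <= d) return false;
          lab[u] -= d;
        } else if (S[st[u]] == 1) {
          lab[u] += d;
        }
      }
      for (int b = n + 1; b <= n_x; ++b)
        if (st[b] == b) {
          if (S[b] == 0) lab[b] += d * 2;
          else if (S[b] == 1) lab[b] -= d * 2;
        }
      q.clear();
      for (int x = 1; x <= n_x; ++x)
        if (st[x] == x && slack_[x] && st[slack_[x]] != x &&
            e_delta(g[slack_[x]][x]) == 0)
          if (on_found_edge(g[slack_[x]][x])) return true;
      for (int b = n + 1; b <= n_x; ++b)
        if (st[b] == b && S[b] == 1 && lab[b] == 0) expand_blossom(b);
    }
  }

  // weights[u][v], 1-based; returns matched partner per vertex (0 if none)
  std::vector<int> solve(const std::vector<std::vector<ll> > &w) {
    for (int u = 1; u <= n; ++u)
      for (int v = 1; v <= n; ++v) g[u][v].w = (u == v) ? 0 : w[u][v];
    n_x = n;
    std::fill(match_.begin(), match_.end(), 0);
    for (int u = 0; u <= n; ++u) { st[u] = u; flower[u].clear(); }
    ll w_max = 0;
    for (int u = 1; u <= n; ++u)
      for (int v = 1; v <= n; ++v) {
        flower_from[u][v] = (u == v ? u : 0);
        w_max = std::max(w_max, g[u][v].w);
      }
    for (int u = 1; u <= n; ++u) lab[u] = w_max;
    while (matching_round()) {}
    std::vector<int> res(n + 1, 0);
    for (int u = 1; u <= n; ++u) res[u] = match_[u];
    return res;
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::IntegerVector mwpm_cpp(Rcpp::NumericMatrix dist) {
  int n = dist.nrow();
  if (n != dist.ncol()) Rcpp::stop("distance matrix must be square");
  if (n % 2 != 0) Rcpp::stop("number of units must be even");
  if (n == 0) return Rcpp::IntegerVector(0);
  double dmax = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double d = dist(i, j);
      if (!R_finite(d) || d < 0) Rcpp::stop("distances must be finite and non-negative");
      if (d > dmax) dmax = d;
    }
  const double SCALE = 1e12;
  std::vector<std::vector<ll> > w(n + 1, std::vector<ll>(n + 1, 0));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      // symmetrize defensively; larger weight = smaller distance
      double d = 0.5 * (dist(i, j) + dist(j, i));
      double frac = (dmax > 0) ? (1.0 - d / dmax) : 1.0;
      w[i + 1][j + 1] = (ll)std::llround(frac * SCALE) + 1;
    }
  Blossom B(n);
  std::vector<int> m = B.solve(w);
  Rcpp::IntegerVector out(n);
  for (int i = 1; i <= n; ++i) out[i - 1] = m[i];
  return out;
}
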