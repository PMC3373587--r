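// Exact stochastic simulation (Gillespie direct and optimized direct
// methods) for mass-action reaction networks, with deterministic
// per-realization random streams and grid-sampled ensemble statistics.
//
// Propensities use the falling-factorial mass-action form: reaction j with
// reactant multiplicities m_1..m_q over species i_1..i_q has
//   a_j(n) = kc_j * prod_q ff(n_iq, m_q),
// where kc_j is the precomputed count-space rate factor
// k_j * omega^(1 - sum_q m_q).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---- RNG: splitmix64 seeding + xoshiro256++ ----------------------------
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  Xoshiro(uint64_t seed, uint64_t stream) {
    uint64_t x = seed * 0x9E3779B97F4A7C15ULL + stream * 0xD1B54A32D192ED03ULL + 1ULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1)
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double expo(double rate) { return -std::log(unif()) / rate; }
};

struct Net {
  int N, R;
  std::vector<double> kc;                    // count-space rate factors
  std::vector<std::vector<std::pair<int,int>>> reac; // (species, multiplicity)
  std::vector<std::vector<std::pair<int,int>>> dS;   // sparse net change
  std::vector<std::vector<int>> deps;        // reactions affected by firing j
};

static Net build_net(const IntegerMatrix &Sr, const IntegerMatrix &Sn,
                     const NumericVector &kc) {
  Net net;
  net.N = Sr.nrow(); net.R = Sr.ncol();
  net.kc.assign(kc.begin(), kc.end());
  net.reac.resize(net.R); net.dS.resize(net.R);
  for (int j = 0; j < net.R; ++j)
    for (int i = 0; i < net.N; ++i) {
      if (Sr(i, j) > 0) net.reac[j].push_back({i, Sr(i, j)});
      if (Sn(i, j) != 0) net.dS[j].push_back({i, Sn(i, j)});
    }
  // dependency graph: j -> all reactions reading a species j changes
  net.deps.resize(net.R);
  for (int j = 0; j < net.R; ++j) {
    for (int k = 0; k < net.R; ++k) {
      bool dep = false;
      for (auto &ci : net.dS[j])
        for (auto &rk : net.reac[k])
          if (ci.first == rk.first) { dep = true; break; }
      if (dep) net.deps[j].push_back(k);
    }
  }
  return net;
}

static inline double propensity(const Net &net, int j,
                                const std::vector<double> &n) {
  double a = net.kc[j];
  for (auto &p : net.reac[j]) {
    double x = n[p.first];
    for (int m = 0; m < p.second; ++m) { a *= (x - m); }
    if (x < p.second) return 0.0;   // depleted: propensity vanishes
  }
  return a > 0 ? a : 0.0;
}

// one realization; records grid samples (right-continuous) and optionally
// the full event sequence up to max_events
struct PathResult {
  NumericMatrix grid_states;
  std::vector<double> ev_t;
  std::vector<std::vector<double>> ev_n;
  bool truncated;
};

static PathResult run_path(const Net &net, std::vector<double> n,
                           const NumericVector &grid, double t_final,
                           Xoshiro &rng, bool odm, int record_events,
                           const std::vector<int> *order_in = nullptr) {
  int G = grid.size();
  PathResult res;
  res.grid_states = NumericMatrix(G, net.N);
  res.truncated = false;

  std::vector<double> a(net.R);
  double a0 = 0;
  for (int j = 0; j < net.R; ++j) { a[j] = propensity(net, j, n); a0 += a[j]; }

  std::vector<int> order(net.R);
  for (int j = 0; j < net.R; ++j) order[j] = j;
  if (odm && order_in) order = *order_in;

  double t = 0;
  int gi = 0;
  auto flush_grid = [&](double tnext) {
    while (gi < G && grid[gi] <= tnext) {
      for (int i = 0; i < net.N; ++i) res.grid_states(gi, i) = n[i];
      ++gi;
    }
  };
  long iter = 0;
  while (true) {
    if ((++iter & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    double tnext = (a0 > 0) ? t + rng.expo(a0) : R_PosInf;
    if (tnext > t_final) { flush_grid(t_final); break; }
    flush_grid(std::nextafter(tnext, 0.0));
    // choose reaction (search in frequency order for ODM)
    double u = rng.unif() * a0, acc = 0;
    int fired = order[net.R - 1];
    for (int q = 0; q < net.R; ++q) {
      int j = order[q];
      acc += a[j];
      if (u <= acc) { fired = j; break; }
    }
    for (auto &ci : net.dS[fired]) n[ci.first] += ci.second;
    // partial propensity update over the dependency graph
    for (int k : net.deps[fired]) {
      double anew = propensity(net, k, n);
      a0 += anew - a[k];
      a[k] = anew;
    }
    if (a0 < 0) a0 = 0;
    // guard against drift in the running total
    if ((iter & 0x3FF) == 0) {
      a0 = 0; for (int j = 0; j < net.R; ++j) a0 += a[j];
    }
    t = tnext;
    if (record_events > 0 && (int)res.ev_t.size() < record_events) {
      res.ev_t.push_back(t);
      res.ev_n.push_back(n);
    } else if (record_events > 0) {
      res.truncated = true;
    }
  }
  return res;
}

// presimulation to estimate firing frequencies for the optimized direct
// method: run up to max_ev events (or t_limit), return descending order
static std::vector<int> odm_order(const Net &net, std::vector<double> n,
                                  double t_limit, long max_ev, Xoshiro &rng) {
  std::vector<long> count(net.R, 0);
  std::vector<double> a(net.R);
  double a0 = 0, t = 0;
  for (int j = 0; j < net.R; ++j) { a[j] = propensity(net, j, n); a0 += a[j]; }
  for (long it = 0; it < max_ev; ++it) {
    if (a0 <= 0) break;
    t += rng.expo(a0);
    if (t > t_limit) break;
    double u = rng.unif() * a0, acc = 0;
    int fired = net.R - 1;
    for (int j = 0; j < net.R; ++j) { acc += a[j]; if (u <= acc) { fired = j; break; } }
    ++count[fired];
    for (auto &ci : net.dS[fired]) n[ci.first] += ci.second;
    for (int k : net.deps[fired]) { double anew = propensity(net, k, n); a0 += anew - a[k]; a[k] = anew; }
  }
  std::vector<int> order(net.R);
  for (int j = 0; j < net.R; ++j) order[j] = j;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a_, int b_) { return count[a_] > count[b_]; });
  return order;
}

// [[Rcpp::export]]
List ssa_path_cpp(IntegerMatrix Sr, IntegerMatrix Sn, NumericVector kc,
                  NumericVector n0, NumericVector grid, double t_final,
                  double seed, double realization, bool odm,
                  int record_events, double odm_t_limit, double odm_max_ev) {
  Net net = build_net(Sr, Sn, kc);
  std::vector<double> n(n0.begin(), n0.end());
  Xoshiro rng((uint64_t)seed, (uint64_t)realization);
  std::vector<int> order;
  if (odm) {
    Xoshiro prng((uint64_t)seed, 0x7F4A7C15ULL);  // presimulation stream
    order = odm_order(net, n, odm_t_limit, (long)odm_max_ev, prng);
  }
  PathResult res = run_path(net, n, grid, t_final, rng, odm,
                            record_events, odm ? &order : nullptr);
  int E = res.ev_t.size();
  NumericVector evt(E);
  NumericMatrix evn(E, net.N);
  for (int e = 0; e < E; ++e) {
    evt[e] = res.ev_t[e];
    for (int i = 0; i < net.N; ++i) evn(e, i) = res.ev_n[e][i];
  }
  return List::create(_["grid_states"] = res.grid_states,
                      _["event_times"] = evt, _["event_states"] = evn,
                      _["truncated"] = res.truncated);
}

// chunk of realizations with streaming (Welford) grid statistics.
// Returns per-grid-point mean (G x N) and co-moment array (G x N x N,
// flattened), plus count, for deterministic combination across chunks.
// [[Rcpp::export]]
List ssa_chunk_cpp(IntegerMatrix Sr, IntegerMatrix Sn, NumericVector kc,
                   NumericVector n0, NumericVector grid, double t_final,
                   double seed, double first_realization, int n_real,
                   bool odm, double odm_t_limit, double odm_max_ev) {
  Net net = build_net(Sr, Sn, kc);
  int G = grid.size(), N = net.N;
  NumericMatrix mean(G, N);
  NumericVector m2(G * N * N);
  std::vector<int> order;
  if (odm) {
    Xoshiro prng((uint64_t)seed, 0x7F4A7C15ULL);
    std::vector<double> n(n0.begin(), n0.end());
    order = odm_order(net, n, odm_t_limit, (long)odm_max_ev, prng);
  }
  for (int r = 0; r < n_real; ++r) {
    std::vector<double> n(n0.begin(), n0.end());
    Xoshiro rng((uint64_t)seed, (uint64_t)(first_realization + r));
    PathResult res = run_path(net, n, grid, t_final, rng, odm, 0,
                              odm ? &order : nullptr);
    double k = r + 1;
    for (int g = 0; g < G; ++g) {
      // Welford update with the full vector
      for (int i = 0; i < N; ++i) {
        double xi = res.grid_states(g, i);
        double di = xi - mean(g, i);
        // co-moment update uses pre-update deltas for all pairs
        for (int i2 = 0; i2 <= i; ++i2) {
          double d2 = res.grid_states(g, i2) - mean(g, i2);
          m2[(size_t)g * N * N + i * N + i2] += di * d2 * (k - 1) / k;
        }
      }
      for (int i = 0; i < N; ++i)
        mean(g, i) += (res.grid_states(g, i) - mean(g, i)) / k;
    }
  }
  // mirror lower triangle
  for (int g = 0; g < G; ++g)
    for (int i = 0; i < N; ++i)
      for (int i2 = i + 1; i2 < N; ++i2)
        m2[(size_t)g * N * N + i * N + i2] =
          m2[(size_t)g * N * N + i2 * N + i];
  return List::create(_["mean"] = mean, _["m2"] = m2, _["n"] = n_real);
}
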