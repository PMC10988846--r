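// Continuous-time asynchronous Boolean dynamics:
//  - Gillespie ensemble simulation (one-node flips at expression-derived
//    up/down rates whenever a node's value disagrees with its rule)
//  - exact transient solution of the 2^m-state master equation by
//    uniformization (non-forced nodes only; forced nodes are frozen).
// A counter-based splitmix64 stream per (seed, trajectory) makes every
// trajectory reproducible in isolation.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline uint64_t splitmix64_next(uint64_t &state) {
  state += 0x9E3779B97F4A7C15ULL;
  uint64_t z = state;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s;
  Rng(uint64_t seed, uint64_t stream) {
    s = seed * 0x9E3779B97F4A7C15ULL + (stream + 1) * 0xBF58476D1CE4E5B9ULL;
    splitmix64_next(s);
    splitmix64_next(s);
  }
  // uniform in [0, 1)
  double unif() {
    return (splitmix64_next(s) >> 11) * (1.0 / 9007199254740992.0);
  }
  // exponential with given rate, strictly positive
  double expo(double rate) { return -std::log1p(-unif()) / rate; }
};

struct Model {
  int n;
  std::vector<std::vector<int>> regs;  // 0-based regulator indices
  std::vector<std::vector<int>> tt;    // truth table per node
  std::vector<double> up, down;
  std::vector<int> forced;             // -1 free, else 0/1
  std::vector<double> init;

  Model(List regs_, List tt_, NumericVector up_, NumericVector down_,
        IntegerVector forced_, NumericVector init_) {
    n = up_.size();
    regs.resize(n); tt.resize(n);
    up.assign(up_.begin(), up_.end());
    down.assign(down_.begin(), down_.end());
    forced.assign(forced_.begin(), forced_.end());
    init.assign(init_.begin(), init_.end());
    for (int i = 0; i < n; ++i) {
      IntegerVector r = regs_[i];
      IntegerVector t = tt_[i];
      regs[i].assign(r.begin(), r.end());
      for (size_t j = 0; j < regs[i].size(); ++j) regs[i][j] -= 1;  // 1->0 based
      tt[i].assign(t.begin(), t.end());
    }
  }

  inline int ruleValue(int i, const std::vector<int> &x) const {
    int idx = 0;
    const std::vector<int> &r = regs[i];
    for (size_t j = 0; j < r.size(); ++j) idx |= x[r[j]] << j;
    return tt[i][idx];
  }
};

// Simulate one trajectory, accumulating state into counts at grid times in
// [segment start, segment end). If record is null, fill path vectors instead.
static void simulate_traj(const Model &m, const NumericVector &grid,
                          Rng &rng, double t_max,
                          std::vector<double> *counts,
                          std::vector<double> *path_t,
                          std::vector<int> *path_x) {
  int n = m.n, G = grid.size();
  std::vector<int> x(n);
  for (int i = 0; i < n; ++i) {
    if (m.forced[i] >= 0) x[i] = m.forced[i];
    else x[i] = (rng.unif() < m.init[i]) ? 1 : 0;
  }
  double t = 0.0;
  int g = 0;
  if (path_t) {
    path_t->push_back(0.0);
    path_x->insert(path_x->end(), x.begin(), x.end());
  }
  std::vector<double> prop(n);
  while (true) {
    double total = 0.0;
    for (int i = 0; i < n; ++i) {
      prop[i] = 0.0;
      if (m.forced[i] >= 0) continue;
      int f = m.ruleValue(i, x);
      if (f != x[i]) prop[i] = f ? m.up[i] : m.down[i];
      total += prop[i];
    }
    double t_next = (total > 0.0) ? t + rng.expo(total) : t_max + 1.0;
    // record grid points passed while in the current state
    if (counts) {
      while (g < G && grid[g] < t_next) {
        for (int i = 0; i < n; ++i) (*counts)[(size_t)i * G + g] += x[i];
        ++g;
      }
    }
    if (t_next > t_max) break;
    t = t_next;
    double u = rng.unif() * total;
    double acc = 0.0;
    int flip = -1;
    for (int i = 0; i < n; ++i) {
      acc += prop[i];
      if (u < acc) { flip = i; break; }
    }
    if (flip < 0) flip = n - 1;  // guard against rounding
    x[flip] = 1 - x[flip];
    if (path_t) {
      path_t->push_back(t);
      path_x->insert(path_x->end(), x.begin(), x.end());
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_gillespie_activity(List regs, List tt, NumericVector up,
                                     NumericVector down, IntegerVector forced,
                                     NumericVector init, NumericVector grid,
                                     int n_traj, double seed) {
  Model m(regs, tt, up, down, forced, init);
  int G = grid.size();
  double t_max = grid[G - 1];
  std::vector<double> counts((size_t)m.n * G, 0.0);
  uint64_t useed = (uint64_t)(int64_t)seed;
  for (int k = 0; k < n_traj; ++k) {
    Rng rng(useed, (uint64_t)k);
    simulate_traj(m, grid, rng, t_max, &counts, nullptr, nullptr);
  }
  NumericMatrix out(m.n, G);
  for (int i = 0; i < m.n; ++i)
    for (int g = 0; g < G; ++g)
      out(i, g) = counts[(size_t)i * G + g] / n_traj;
  return out;
}

// [[Rcpp::export]]
List cpp_gillespie_path(List regs, List tt, NumericVector up,
                        NumericVector down, IntegerVector forced,
                        NumericVector init, double t_max, double seed,
                        int traj_index) {
  Model m(regs, tt, up, down, forced, init);
  NumericVector dummy = NumericVector::create(t_max);
  std::vector<double> pt;
  std::vector<int> px;
  uint64_t useed = (uint64_t)(int64_t)seed;
  Rng rng(useed, (uint64_t)traj_index);
  simulate_traj(m, dummy, rng, t_max, nullptr, &pt, &px);
  int k = pt.size();
  NumericVector times(pt.begin(), pt.end());
  IntegerMatrix states(k, m.n);
  for (int r = 0; r < k; ++r)
    for (int i = 0; i < m.n; ++i)
      states(r, i) = px[(size_t)r * m.n + i];
  return List::create(_["times"] = times, _["states"] = states);
}

// Exact marginal activities from the master equation via uniformization.
// Returns the node x grid activity matrix plus the worst probability-mass
// defect over the grid (truncation diagnostics).
// [[Rcpp::export]]
List cpp_exact_activity(List regs, List tt, NumericVector up,
                        NumericVector down, IntegerVector forced,
                        NumericVector init, NumericVector grid,
                        int cap, double tol) {
  Model m(regs, tt, up, down, forced, init);
  int n = m.n, G = grid.size();
  std::vector<int> free_idx;
  for (int i = 0; i < n; ++i) if (m.forced[i] < 0) free_idx.push_back(i);
  int mm = free_idx.size();
  if (mm > cap)
    stop("state space 2^%d exceeds the exact-solver cap (%d non-forced "
         "nodes > cap %d); use the Monte Carlo engine", mm, mm, cap);
  size_t S = (size_t)1 << mm;

  // eligible flips per state in CSR layout (targets + rates), plus the
  // uniformized diagonal 1 - outrate/lambda
  std::vector<size_t> row_ptr(S + 1, 0);
  std::vector<size_t> targ;
  std::vector<double> tr_rate;
  std::vector<double> outrate(S, 0.0);
  targ.reserve(S * mm / 2 + 1);
  tr_rate.reserve(S * mm / 2 + 1);
  std::vector<int> x(n);
  for (int i = 0; i < n; ++i) if (m.forced[i] >= 0) x[i] = m.forced[i];
  for (size_t s = 0; s < S; ++s) {
    for (int j = 0; j < mm; ++j) x[free_idx[j]] = (int)((s >> j) & 1);
    for (int j = 0; j < mm; ++j) {
      int i = free_idx[j];
      int f = m.ruleValue(i, x);
      if (f != x[i]) {
        double r = f ? m.up[i] : m.down[i];
        targ.push_back(s ^ ((size_t)1 << j));
        tr_rate.push_back(r);
        outrate[s] += r;
      }
    }
    row_ptr[s + 1] = targ.size();
  }
  double lambda = 0.0;
  for (int j = 0; j < mm; ++j) {
    int i = free_idx[j];
    lambda += std::max(m.up[i], m.down[i]);
  }
  if (lambda <= 0.0) lambda = 1.0;
  std::vector<double> diag(S);
  for (size_t s = 0; s < S; ++s) diag[s] = 1.0 - outrate[s] / lambda;
  double inv_lambda = 1.0 / lambda;

  // initial distribution: independent Bernoulli over free nodes
  std::vector<double> p(S, 1.0);
  for (size_t s = 0; s < S; ++s)
    for (int j = 0; j < mm; ++j) {
      double pi = m.init[free_idx[j]];
      p[s] *= ((s >> j) & 1) ? pi : (1.0 - pi);
    }

  NumericMatrix act(n, G);
  double mass_err = 0.0;
  std::vector<double> v(S), acc(S), vn(S);

  auto record = [&](int g) {
    double mass = 0.0;
    for (size_t s = 0; s < S; ++s) mass += p[s];
    mass_err = std::max(mass_err, std::fabs(1.0 - mass));
    for (int i = 0; i < n; ++i)
      if (m.forced[i] >= 0) act(i, g) = m.forced[i];
    for (int j = 0; j < mm; ++j) {
      double a = 0.0;
      for (size_t s = 0; s < S; ++s) if ((s >> j) & 1) a += p[s];
      act(free_idx[j], g) = a;
    }
  };

  double t_prev = 0.0;
  for (int g = 0; g < G; ++g) {
    double dt = grid[g] - t_prev;
    if (g == 0 && grid[0] == 0.0) { record(0); continue; }
    if (dt > 0.0) {
      double ldt = lambda * dt;
      double w = std::exp(-ldt);
      double cum = w;
      v = p;
      for (size_t s = 0; s < S; ++s) acc[s] = w * v[s];
      int kmax = (int)std::ceil(ldt + 10.0 * std::sqrt(ldt + 1.0)) + 50;
      for (int k = 1; k <= kmax && (1.0 - cum) > tol; ++k) {
        // v <- P v with P = I + Q/lambda (probability-flow form)
        for (size_t s = 0; s < S; ++s) vn[s] = diag[s] * v[s];
        for (size_t s = 0; s < S; ++s) {
          double vs = v[s] * inv_lambda;
          for (size_t e = row_ptr[s]; e < row_ptr[s + 1]; ++e)
            vn[targ[e]] += vs * tr_rate[e];
        }
        v.swap(vn);
        w *= ldt / k;
        cum += w;
        for (size_t s = 0; s < S; ++s) acc[s] += w * v[s];
      }
      p = acc;
    }
    record(g);
    t_prev = grid[g];
  }
  return List::create(_["activity"] = act, _["mass_err"] = mass_err);
}
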