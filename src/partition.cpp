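#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dense-subgraph partitioning of a weighted directed graph, split into the
// seeding stage (cover-free sampling) and the association-score
// optimization sweep. Graphs arrive as two CSC structures: `out` columns
// list each node's outgoing neighbors, `in` columns its incoming ones.
// All RNG draws go through R's generator, so set.seed() on the R side
// makes every run reproducible.

static int sample_weighted_cube(const std::vector<double> &f,
                                const std::vector<char> &covered) {
  double total = 0.0;
  for (size_t i = 0; i < f.size(); ++i)
    if (!covered[i]) total += f[i] * f[i] * f[i];
  if (total <= 0.0) return -1;
  double r = unif_rand() * total, acc = 0.0;
  for (size_t i = 0; i < f.size(); ++i) {
    if (covered[i]) continue;
    acc += f[i] * f[i] * f[i];
    if (r <= acc) return (int)i;
  }
  for (int i = (int)f.size() - 1; i >= 0; --i) if (!covered[i]) return i;
  return -1;
}

// Seeding: repeatedly draw an uncovered seed with probability proportional
// to the cube of its cover-free score f(i) = |N_out(i) - C|, claim the
// seed plus its uncovered out-neighbors as a new subgraph, until no
// uncovered cell has more than size_min uncovered out-neighbors.
static int seed_stage(const int *out_p, const int *out_i,
                      const int *in_p, const int *in_i,
                      int n, int size_min, std::vector<int> &mc) {
  std::vector<char> covered(n, 0);
  std::vector<double> f(n);
  for (int i = 0; i < n; ++i) f[i] = out_p[i + 1] - out_p[i];
  int k = 0;
  for (;;) {
    double fmax = -1.0;
    for (int i = 0; i < n; ++i)
      if (!covered[i] && f[i] > fmax) fmax = f[i];
    if (fmax <= (double)size_min) break;
    int j = sample_weighted_cube(f, covered);
    if (j < 0) break;
    // claim j and its uncovered out-neighbors
    std::vector<int> claimed;
    claimed.push_back(j);
    for (int e = out_p[j]; e < out_p[j + 1]; ++e)
      if (!covered[out_i[e]]) claimed.push_back(out_i[e]);
    for (int u : claimed) {
      mc[u] = k;
      covered[u] = 1;
    }
    // a newly covered u decrements f of every in-neighbor
    for (int u : claimed)
      for (int e = in_p[u]; e < in_p[u + 1]; ++e)
        f[in_i[e]] -= 1.0;
    ++k;
  }
  return k;
}

struct OptResult { bool converged; int passes; long long edge_visits; };

// Optimization sweep: visit cells in a reshuffled random order each pass
// and reassign each to the subgraph maximizing
//   w_ik = wi_ik * wo_ik / |M_k|^2,
// the product of its incoming and outgoing edge-weight association,
// normalized by subgraph size. The score of staying put is inflated by
// stickiness^pass, which forces convergence. Cells whose products are all
// zero but that do touch an assigned neighbor fall back to the additive
// score wi + wo, so every cell in a large-enough component ends up
// assigned; cells in components too small to seed stay at -1.
static OptResult optimize_stage(const int *out_p, const int *out_i,
                                const double *out_w, const int *in_p,
                                const int *in_i, const double *in_w, int n,
                                int n_sub, int max_passes, double stickiness,
                                std::vector<int> &mc) {
  std::vector<double> sizes(n_sub + 1, 0.0);
  int kmax = n_sub;
  for (int i = 0; i < n; ++i) if (mc[i] >= 0) sizes[mc[i]] += 1.0;
  std::vector<double> wo(kmax + n + 1, 0.0), wi(kmax + n + 1, 0.0);
  std::vector<int> touched;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  OptResult res = {false, 0, 0};

  for (int pass = 1; pass <= max_passes; ++pass) {
    // Fisher-Yates reshuffle from R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double stick = std::pow(stickiness, (double)pass);
    bool moved = false;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      touched.clear();
      for (int e = out_p[i]; e < out_p[i + 1]; ++e) {
        int k = mc[out_i[e]];
        if (k < 0) continue;
        if (wo[k] == 0.0 && wi[k] == 0.0) touched.push_back(k);
        wo[k] += out_w[e];
        ++res.edge_visits;
      }
      for (int e = in_p[i]; e < in_p[i + 1]; ++e) {
        int k = mc[in_i[e]];
        if (k < 0) continue;
        if (wo[k] == 0.0 && wi[k] == 0.0) touched.push_back(k);
        wi[k] += in_w[e];
        ++res.edge_visits;
      }
      int cur = mc[i], best = -1;
      double best_w = 0.0;
      for (int k : touched) {
        double w = wi[k] * wo[k] / (sizes[k] * sizes[k]);
        if (k == cur) w *= stick;
        if (w > best_w || (w == best_w && w > 0.0 &&
                           (k == cur || (best != cur && k < best)))) {
          best_w = w; best = k;
        }
      }
      if (best < 0) {
        // product score is zero everywhere: fall back to wi + wo so the
        // cell can attach to any assigned neighbor at all
        double best_s = 0.0;
        for (int k : touched) {
          double s = (wi[k] + wo[k]) / sizes[k];
          if (k == cur) s *= stick;
          if (s > best_s || (s == best_s && s > 0.0 &&
                             (k == cur || (best != cur && k < best)))) {
            best_s = s; best = k;
          }
        }
      }
      for (int k : touched) { wo[k] = 0.0; wi[k] = 0.0; }
      if (best >= 0 && best != cur) {
        if (cur >= 0) sizes[cur] -= 1.0;
        sizes[best] += 1.0;
        mc[i] = best;
        moved = true;
      }
    }
    res.passes = pass;
    if (!moved) { res.converged = true; break; }
  }
  return res;
}

// [[Rcpp::export(name = ".cpp_partition")]]
List cpp_partition(IntegerVector out_p, IntegerVector out_i,
                   NumericVector out_w, IntegerVector in_p,
                   IntegerVector in_i, NumericVector in_w, int n,
                   int size_min, int max_passes, double stickiness,
                   IntegerVector init_mc, bool do_seed, bool do_optimize) {
  std::vector<int> mc(n, -1);
  int n_seeds = 0;
  if (do_seed) {
    n_seeds = seed_stage(out_p.begin(), out_i.begin(), in_p.begin(),
                         in_i.begin(), n, size_min, mc);
  } else {
    if (init_mc.size() != n) stop("init_mc must have one entry per node");
    for (int i = 0; i < n; ++i) mc[i] = init_mc[i];
    for (int i = 0; i < n; ++i) if (mc[i] + 1 > n_seeds) n_seeds = mc[i] + 1;
  }
  bool converged = true; int passes = 0; long long visits = 0;
  if (do_optimize && n_seeds > 0) {
    OptResult r = optimize_stage(out_p.begin(), out_i.begin(), out_w.begin(),
                                 in_p.begin(), in_i.begin(), in_w.begin(), n,
                                 n_seeds, max_passes, stickiness, mc);
    converged = r.converged; passes = r.passes; visits = r.edge_visits;
  }
  return List::create(_["mc"] = IntegerVector(mc.begin(), mc.end()),
                      _["n_seeds"] = n_seeds, _["converged"] = converged,
                      _["passes"] = passes,
                      _["edge_visits"] = (double)visits);
}

// Accumulate bootstrap co-occurrence tallies: `cells` are the 0-based
// original indices sampled in this resample, `mc` their subgraph labels
// (-1 = unassigned). o(i,j) counts co-sampling, c(i,j) co-assignment;
// only the upper triangle (and diagonal) is touched.
// [[Rcpp::export(name = ".cpp_tally_cooc")]]
void cpp_tally_cooc(IntegerVector cells, IntegerVector mc, IntegerMatrix o,
                    IntegerMatrix c) {
  int m = cells.size();
  for (int a = 0; a < m; ++a) {
    for (int b = a; b < m; ++b) {
      int i = cells[a], j = cells[b];
      int lo = i < j ? i : j, hi = i < j ? j : i;
      o(lo, hi) += 1;
      if (mc[a] >= 0 && mc[a] == mc[b]) c(lo, hi) += 1;
    }
  }
}
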