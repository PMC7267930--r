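// Dense Louvain modularity maximization for signed weighted graphs.
//
// The quality function is Q = a_p * Qhat(W+) - a_n * Qhat(W-), where W+/-
// are the positive/negative parts of the matrix, Qhat the Newman-Girvan
// modularity with resolution gamma computed on one part, and the
// coefficients depend on the variant:
//   signed:   a_p = 1, a_n = v- / (v+ + v-)   (asymmetric signed quality)
//   positive: a_p = 1, a_n = 0, negative edges discarded
//   plain:    Newman-Girvan applied to the raw (possibly signed) matrix
// Node sweep order is shuffled by a per-run seed (std::mt19937), so results
// are reproducible across platforms for a given seed.
//
// The edge contributions of both parts are folded into one effective matrix
// We = a_p * W+ / 2m+ - a_n * W- / 2m-, precomputed once per graph and
// shared across restarts; only the degree-null terms need the per-part
// strengths. The hot loop walks We row-wise (the parts are symmetric), so
// it streams contiguous memory.

#include <Rcpp.h>
#include <random>
#include <numeric>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Graph {
  int n;
  std::vector<double> Wp, Wn; // column-major n x n
};

// per-graph quantities reused by every restart on that graph
struct LevelData {
  std::vector<double> We;     // folded effective edge matrix
  std::vector<double> kp, kn; // per-node strengths (self-loops included)
  double gamma, cp, cn, m2p, m2n;
};

// strengths including self-loops (k_i = sum_j w_ij, 2m = sum_i k_i)
static void strengths(const std::vector<double>& W, int n,
                      std::vector<double>& k) {
  k.assign(n, 0.0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      k[i] += W[i + (size_t)j * n];
}

static LevelData make_level_data(const Graph& g, double gamma, double ap,
                                 double an, double m2p, double m2n) {
  LevelData ld;
  ld.gamma = gamma;
  ld.m2p = m2p;
  ld.m2n = m2n;
  ld.cp = (m2p > 0.0) ? ap / m2p : 0.0;
  ld.cn = (m2n > 0.0) ? an / m2n : 0.0;
  const size_t nn = (size_t)g.n * g.n;
  ld.We.resize(nn);
  for (size_t e = 0; e < nn; ++e)
    ld.We[e] = ld.cp * g.Wp[e] - ld.cn * g.Wn[e];
  strengths(g.Wp, g.n, ld.kp);
  strengths(g.Wn, g.n, ld.kn);
  return ld;
}

// one local-move phase; comm gets the per-node community (0..n-1, sparse ids)
static bool one_level(int n, const LevelData& ld, std::vector<int>& comm,
                      double tol, std::mt19937& rng) {
  std::vector<double> Kp(ld.kp), Kn(ld.kn); // community strengths
  comm.resize(n);
  std::iota(comm.begin(), comm.end(), 0);

  std::vector<double> wto(n, 0.0);
  std::vector<char> seen(n, 0);
  std::vector<int> touched;
  touched.reserve(n);
  std::vector<int> order(n);
  std::iota(order.begin(), order.end(), 0);

  const double np_scale = 2.0 * ld.gamma * ld.cp / (ld.m2p > 0.0 ? ld.m2p : 1.0);
  const double nn_scale = 2.0 * ld.gamma * ld.cn / (ld.m2n > 0.0 ? ld.m2n : 1.0);

  bool any_move = false;
  bool moved = true;
  int sweep = 0;
  while (moved && sweep < 1000) {
    moved = false;
    ++sweep;
    std::shuffle(order.begin(), order.end(), rng);
    for (int oi = 0; oi < n; ++oi) {
      const int i = order[oi];
      const int a = comm[i];
      touched.clear();
      const double* row = &ld.We[(size_t)i * n]; // row i (We is symmetric)
      for (int j = 0; j < n; ++j) {
        const double w = row[j];
        if (w != 0.0 && j != i) {
          const int c = comm[j];
          if (!seen[c]) { seen[c] = 1; touched.push_back(c); }
          wto[c] += w;
        }
      }
      if (!seen[a]) { seen[a] = 1; touched.push_back(a); }

      const double KpA = Kp[a] - ld.kp[i];
      const double KnA = Kn[a] - ld.kn[i];
      const double nip = np_scale * ld.kp[i]; // null-term coefficients, node i
      const double nin = nn_scale * ld.kn[i];
      const double wa = wto[a];
      double best_gain = tol;
      int best_c = a;
      for (size_t t = 0; t < touched.size(); ++t) {
        const int b = touched[t];
        if (b == a) continue;
        const double gain = 2.0 * (wto[b] - wa) -
                            nip * (Kp[b] - KpA) + nin * (Kn[b] - KnA);
        if (gain > best_gain) {
          best_gain = gain;
          best_c = b;
        }
      }
      if (best_c != a) {
        comm[i] = best_c;
        Kp[a] -= ld.kp[i]; Kn[a] -= ld.kn[i];
        Kp[best_c] += ld.kp[i]; Kn[best_c] += ld.kn[i];
        moved = true;
        any_move = true;
      }
      for (size_t t = 0; t < touched.size(); ++t) {
        wto[touched[t]] = 0.0;
        seen[touched[t]] = 0;
      }
    }
  }
  return any_move;
}

// relabel communities to 0..k-1 by first appearance; returns k
static int renumber(std::vector<int>& comm) {
  std::vector<int> map(comm.size(), -1);
  int k = 0;
  for (size_t i = 0; i < comm.size(); ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = k++;
    comm[i] = map[comm[i]];
  }
  return k;
}

// collapse communities into nodes; self-loops carry internal weight
static Graph aggregate(const Graph& g, const std::vector<int>& comm, int k) {
  Graph h;
  h.n = k;
  h.Wp.assign((size_t)k * k, 0.0);
  h.Wn.assign((size_t)k * k, 0.0);
  for (int j = 0; j < g.n; ++j) {
    const int cj = comm[j];
    for (int i = 0; i < g.n; ++i) {
      const int ci = comm[i];
      h.Wp[ci + (size_t)cj * k] += g.Wp[i + (size_t)j * g.n];
      h.Wn[ci + (size_t)cj * k] += g.Wn[i + (size_t)j * g.n];
    }
  }
  return h;
}

// full quality of a membership from the precomputed level data:
// Q = sum_{c_i = c_j} We_ij - gamma * (cp * sum_c Kp_c^2 / 2m+ -
//                                      cn * sum_c Kn_c^2 / 2m-)
static double full_q(int n, const LevelData& ld, const std::vector<int>& comm) {
  const int k = 1 + *std::max_element(comm.begin(), comm.end());
  double edge = 0.0;
  for (int j = 0; j < n; ++j) {
    const int cj = comm[j];
    const double* col = &ld.We[(size_t)j * n];
    for (int i = 0; i < n; ++i)
      if (comm[i] == cj) edge += col[i];
  }
  std::vector<double> Kp(k, 0.0), Kn(k, 0.0);
  for (int i = 0; i < n; ++i) {
    Kp[comm[i]] += ld.kp[i];
    Kn[comm[i]] += ld.kn[i];
  }
  double nullp = 0.0, nulln = 0.0;
  for (int c = 0; c < k; ++c) {
    nullp += Kp[c] * Kp[c];
    nulln += Kn[c] * Kn[c];
  }
  double q = edge;
  if (ld.m2p > 0.0) q -= ld.gamma * ld.cp * nullp / ld.m2p;
  if (ld.m2n > 0.0) q += ld.gamma * ld.cn * nulln / ld.m2n;
  return q;
}

// one complete Louvain run (local moves + aggregation passes); level 1
// reads the shared LevelData, later levels build their own
static std::vector<int> louvain_run(const Graph& g0, const LevelData& ld0,
                                    double ap, double an, double tol,
                                    int max_pass, unsigned seed) {
  std::mt19937 rng(seed);
  std::vector<int> membership(g0.n);
  std::iota(membership.begin(), membership.end(), 0);
  Graph g;            // aggregated graph (level >= 2)
  bool aggregated = false;
  for (int pass = 0; pass < max_pass; ++pass) {
    const Graph& cur = aggregated ? g : g0;
    std::vector<int> comm;
    bool improved;
    if (!aggregated) {
      improved = one_level(cur.n, ld0, comm, tol, rng);
    } else {
      const LevelData ld = make_level_data(cur, ld0.gamma, ap, an, ld0.m2p,
                                           ld0.m2n);
      improved = one_level(cur.n, ld, comm, tol, rng);
    }
    const int k = renumber(comm);
    for (size_t i = 0; i < membership.size(); ++i)
      membership[i] = comm[membership[i]];
    if (!improved || k == cur.n) break;
    g = aggregate(cur, comm, k);
    aggregated = true;
  }
  return membership;
}

// build the signed decomposition for a variant from a dense matrix slice
static Graph make_graph(const double* W, int n, const std::string& variant) {
  Graph g;
  g.n = n;
  g.Wp.assign((size_t)n * n, 0.0);
  g.Wn.assign((size_t)n * n, 0.0);
  const bool plain = (variant == "plain");
  const bool keep_neg = (variant == "signed");
  for (size_t e = 0; e < (size_t)n * n; ++e) {
    const double w = W[e];
    if (!R_finite(w)) stop("matrix entries must be finite");
    if (plain) {
      g.Wp[e] = w;
    } else if (w > 0.0) {
      g.Wp[e] = w;
    } else if (w < 0.0 && keep_neg) {
      g.Wn[e] = -w;
    }
  }
  return g;
}

struct BestResult {
  std::vector<int> assignment;
  double q;
  int k;
  int seed;
  std::vector<double> run_q;
};

static BestResult best_over_seeds(const Graph& g, double gamma,
                                  const int* seeds, int n_seeds,
                                  const std::string& variant, double tol,
                                  int max_pass) {
  const double m2p = std::accumulate(g.Wp.begin(), g.Wp.end(), 0.0);
  const double m2n = std::accumulate(g.Wn.begin(), g.Wn.end(), 0.0);
  if (variant == "plain" && m2p <= 0.0)
    stop("plain quality undefined: total weight must be positive");
  if (m2p + m2n <= 0.0)
    stop("quality undefined for an all-zero matrix");
  double ap = 1.0;
  double an = (variant == "signed" && m2n > 0.0) ? m2n / (m2p + m2n) : 0.0;
  if (m2p <= 0.0) { // negative-only graph under the signed variant
    ap = 0.0;
    an = 1.0;
  }
  const LevelData ld = make_level_data(g, gamma, ap, an, m2p, m2n);
  BestResult out;
  out.q = R_NegInf;
  out.seed = NA_INTEGER;
  out.run_q.resize(n_seeds);
  for (int s = 0; s < n_seeds; ++s) {
    std::vector<int> m = louvain_run(g, ld, ap, an, tol, max_pass,
                                     (unsigned)seeds[s]);
    renumber(m);
    const double q = full_q(g.n, ld, m);
    out.run_q[s] = q;
    if (q > out.q) { // strict: ties resolve to the earliest (lowest) seed
      out.q = q;
      out.assignment = m;
      out.seed = seeds[s];
    }
  }
  out.k = 1 + *std::max_element(out.assignment.begin(), out.assignment.end());
  return out;
}

} // namespace

// [[Rcpp::export]]
List louvain_best_cpp(NumericMatrix W, double gamma, IntegerVector seeds,
                      std::string variant, double tol, int max_pass) {
  const int n = W.nrow();
  if (W.ncol() != n) stop("matrix must be square");
  Graph g = make_graph(W.begin(), n, variant);
  BestResult b = best_over_seeds(g, gamma, seeds.begin(), seeds.size(),
                                 variant, tol, max_pass);
  IntegerVector assignment(n);
  for (int i = 0; i < n; ++i) assignment[i] = b.assignment[i] + 1; // 1-based
  return List::create(_["assignment"] = assignment, _["q"] = b.q,
                      _["n_modules"] = b.k, _["run_seed"] = b.seed,
                      _["run_q"] = wrap(b.run_q));
}

// batch variant: one call per connectivity stack (n x n x n_win array);
// window w uses restart seeds seeds[w], seeds[w] + 1, ..., + n_runs - 1
// [[Rcpp::export]]
List louvain_stack_cpp(NumericVector arr, int n, int n_win, double gamma,
                       IntegerVector window_seeds, int n_runs,
                       std::string variant, double tol, int max_pass) {
  if ((R_xlen_t)n * n * n_win != arr.size())
    stop("array dimensions do not match");
  if (window_seeds.size() != n_win) stop("one base seed per window required");
  IntegerMatrix assignment(n, n_win);
  NumericVector q(n_win);
  IntegerVector n_modules(n_win), run_seed(n_win);
  std::vector<int> seeds(n_runs);
  for (int w = 0; w < n_win; ++w) {
    for (int s = 0; s < n_runs; ++s) seeds[s] = window_seeds[w] + s;
    Graph g = make_graph(&arr[(size_t)w * n * n], n, variant);
    BestResult b = best_over_seeds(g, gamma, seeds.data(), n_runs, variant,
                                   tol, max_pass);
    for (int i = 0; i < n; ++i) assignment(i, w) = b.assignment[i] + 1;
    q[w] = b.q;
    n_modules[w] = b.k;
    run_seed[w] = b.seed;
  }
  return List::create(_["assignment"] = assignment, _["q"] = q,
                      _["n_modules"] = n_modules, _["run_seed"] = run_seed);
}
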