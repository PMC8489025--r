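// Generative HexMaze navigator: no-reversal random search, diagonal runs to
// the outer ring (per-step probability eta), and exponential-foresight direct
// goal runs (mean F). Uses R's RNG so set.seed() governs reproducibility.
#include <Rcpp.h>
using namespace Rcpp;

typedef std::vector<std::vector<int> > AdjList;

static AdjList as_adjlist(const List& adj) {
  AdjList out(adj.size());
  for (int i = 0; i < adj.size(); ++i) {
    IntegerVector nb = adj[i];
    out[i].assign(nb.begin(), nb.end());
  }
  return out;
}

static int sample_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Append one geodesic from u to b (nodes after u, ending at b), sampled
// uniformly among all geodesics: at each node the next step is chosen with
// probability proportional to the number of geodesics continuing through it.
// The first step may not revisit `avoid` (the previously occupied node, the
// no-reversal rule); if every geodesic starts there, nothing is appended and
// false is returned.
static bool append_geodesic(const AdjList& adj, const IntegerMatrix& dist,
                            const NumericMatrix& np, int u, int b, int avoid,
                            std::vector<int>& out) {
  int cur = u;
  bool first = true;
  while (cur != b) {
    double tot = 0.0;
    std::vector<int> cand;
    std::vector<double> w;
    const std::vector<int>& nb = adj[cur - 1];
    for (size_t i = 0; i < nb.size(); ++i) {
      int v = nb[i];
      if (first && v == avoid) continue;
      if (dist(v - 1, b - 1) == dist(cur - 1, b - 1) - 1) {
        cand.push_back(v);
        w.push_back(np(v - 1, b - 1));
        tot += np(v - 1, b - 1);
      }
    }
    if (cand.empty()) return false; // only possible on the first step
    double r = unif_rand() * tot;
    int chosen = cand.back();
    for (size_t i = 0; i < cand.size(); ++i) {
      r -= w[i];
      if (r <= 0) { chosen = cand[i]; break; }
    }
    out.push_back(chosen);
    cur = chosen;
    first = false;
  }
  return true;
}

static std::vector<int> sim_one(const AdjList& adj, const IntegerMatrix& dist,
                                const NumericMatrix& np,
                                const std::vector<int>& outer_nodes,
                                int start, int goal, double eta, double F,
                                int max_steps, bool& completed) {
  std::vector<int> nodes;
  nodes.push_back(start);
  int cur = start, prev = 0, steps = 0;
  bool in_run = false;
  std::vector<int> run;
  size_t runpos = 0;
  completed = false;
  while (true) {
    if (cur == goal) { completed = true; break; }
    // foresight check at every node arrival, including during diagonal runs;
    // a trigger whose only geodesic would immediately reverse is ignored
    if (F > 0) {
      double x = R::rexp(F);
      if ((double)dist(cur - 1, goal - 1) < x &&
          append_geodesic(adj, dist, np, cur, goal, prev, nodes)) {
        completed = true;
        break;
      }
    }
    if (steps >= max_steps) break; // censored
    if (!in_run && eta > 0 && unif_rand() < eta) {
      // diagonal run toward a random outer-ring node at distance >= 3;
      // the geodesic is sampled once, at selection time
      std::vector<int> targets;
      for (size_t i = 0; i < outer_nodes.size(); ++i)
        if (dist(cur - 1, outer_nodes[i] - 1) >= 3) targets.push_back(outer_nodes[i]);
      if (!targets.empty()) {
        int tgt = targets[sample_int((int)targets.size())];
        run.clear();
        if (append_geodesic(adj, dist, np, cur, tgt, prev, run)) {
          runpos = 0;
          in_run = true;
        } // else: the run would reverse immediately; stay in search mode
      }
    }
    int nxt;
    if (in_run) {
      nxt = run[runpos++];
      if (runpos >= run.size()) in_run = false; // target reached: resume search
    } else {
      const std::vector<int>& nb = adj[cur - 1];
      std::vector<int> opts;
      for (size_t i = 0; i < nb.size(); ++i)
        if (nb[i] != prev) opts.push_back(nb[i]); // no immediate reversal
      nxt = opts[sample_int((int)opts.size())];
    }
    nodes.push_back(nxt);
    prev = cur;
    cur = nxt;
    ++steps;
  }
  return nodes;
}

static std::vector<int> outer_vec(const LogicalVector& outer) {
  std::vector<int> v;
  for (int i = 0; i < outer.size(); ++i)
    if (outer[i]) v.push_back(i + 1);
  return v;
}

// [[Rcpp::export]]
IntegerVector sim_trial_cpp(List adj, IntegerMatrix dist, NumericMatrix npaths,
                            LogicalVector outer, int start, int goal,
                            double eta, double F, int max_steps) {
  AdjList a = as_adjlist(adj);
  std::vector<int> on = outer_vec(outer);
  bool completed = false;
  std::vector<int> nodes = sim_one(a, dist, npaths, on, start, goal, eta, F,
                                   max_steps, completed);
  IntegerVector out(nodes.begin(), nodes.end());
  out.attr("completed") = completed;
  return out;
}

// [[Rcpp::export]]
List sim_dataset_cpp(List adj, IntegerMatrix dist, NumericMatrix npaths,
                     LogicalVector outer, IntegerVector starts,
                     IntegerVector goals, int n_reps, double eta, double F,
                     int max_steps) {
  AdjList a = as_adjlist(adj);
  std::vector<int> on = outer_vec(outer);
  int n = starts.size();
  List nodes(n * n_reps);
  LogicalVector completed(n * n_reps);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    for (int r = 0; r < n_reps; ++r, ++k) {
      bool comp = false;
      std::vector<int> tr = sim_one(a, dist, npaths, on, starts[i], goals[i],
                                    eta, F, max_steps, comp);
      nodes[k] = IntegerVector(tr.begin(), tr.end());
      completed[k] = comp;
    }
  }
  return List::create(_["nodes"] = nodes, _["completed"] = completed,
                      _["spec"] = rep_each(seq_len(n), n_reps));
}

// Summary statistics (RTL, max DFOP, outer-ring fraction) of simulated runs,
// without materializing trajectories: used by the (eta, F) grid search.
// dfop[[i]] is the per-node distance to the geodesic set of pair i.
// [[Rcpp::export]]
NumericMatrix sim_stats_cpp(List adj, IntegerMatrix dist, NumericMatrix npaths,
                            LogicalVector outer, IntegerVector starts,
                            IntegerVector goals, IntegerVector reps, List dfop,
                            double eta, double F, int max_steps) {
  AdjList a = as_adjlist(adj);
  std::vector<int> on = outer_vec(outer);
  int n = starts.size(), total = 0;
  for (int i = 0; i < n; ++i) total += reps[i];
  NumericMatrix out(total, 5);
  colnames(out) = CharacterVector::create("pair", "rtl", "max_dfop",
                                          "outer_fraction", "completed");
  int k = 0;
  for (int i = 0; i < n; ++i) {
    NumericVector dv = dfop[i];
    int d0 = dist(starts[i] - 1, goals[i] - 1);
    for (int r = 0; r < reps[i]; ++r, ++k) {
      bool comp = false;
      std::vector<int> tr = sim_one(a, dist, npaths, on, starts[i], goals[i],
                                    eta, F, max_steps, comp);
      double mx = 0.0, of = 0.0;
      for (size_t s = 0; s < tr.size(); ++s) {
        if (dv[tr[s] - 1] > mx) mx = dv[tr[s] - 1];
        if (outer[tr[s] - 1]) of += 1.0;
      }
      out(k, 0) = i + 1;
      out(k, 1) = (double)(tr.size() - 1) / (double)d0;
      out(k, 2) = mx;
      out(k, 3) = of / (double)tr.size();
      out(k, 4) = comp ? 1.0 : 0.0;
    }
  }
  return out;
}
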