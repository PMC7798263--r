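// Exact branch-and-bound search for the binary program underlying
// non-intersecting path selection:
//   maximize sum(x) subject to
//     - pairwise conflicts        x_a + x_b <= 1      (crossing / merge rules)
//     - flow balance per node     sum(out) == sum(in) (middle layers only)
//     - coverage                  sum over a set >= 1 (favored paths)
// Variables are edges. The search assigns variables in a fixed order
// (most-conflicted first), propagates conflicts on 1-assignments, maintains
// running feasibility counters for flow and coverage constraints, and prunes
// with the bound (current + undecided). It is exhaustive up to pruning, so
// the returned objective is a proven optimum and, with the fixed variable
// order, the returned assignment is deterministic.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Flow { // sum(in) == sum(out)
  std::vector<int> in, out;
  int in_sel, in_und, out_sel, out_und;
};

struct Cover { // sum >= 1
  std::vector<int> mem;
  int sel, und;
};

struct Solver {
  int n;
  std::vector<std::vector<int>> confl;          // conflict adjacency
  std::vector<std::vector<int>> var_flow_in;    // flow ids where var is an in-edge
  std::vector<std::vector<int>> var_flow_out;
  std::vector<std::vector<int>> var_cover;
  std::vector<Flow> flows;
  std::vector<Cover> covers;
  std::vector<int> state;                       // -1 undecided, 0, 1
  std::vector<int> order;
  std::vector<int> trail;
  int cur, und, best;
  std::vector<int> best_assign;
  long long nodes;

  // Counter updates must complete before any feasibility verdict: undo_to
  // reverses every counter touched by a trailed variable, so a mid-loop
  // early return would leave the undo out of sync with the updates.
  bool assign(int v, int val) {
    if (state[v] != -1) return state[v] == val;
    state[v] = val;
    trail.push_back(v);
    und--;
    if (val == 1) cur++;
    for (int f : var_flow_in[v]) { flows[f].in_und--; flows[f].in_sel += val; }
    for (int f : var_flow_out[v]) { flows[f].out_und--; flows[f].out_sel += val; }
    for (int c : var_cover[v]) { covers[c].und--; covers[c].sel += val; }
    for (int f : var_flow_in[v]) {
      const Flow &fl = flows[f];
      if (fl.in_sel > fl.out_sel + fl.out_und) return false;
      if (fl.out_sel > fl.in_sel + fl.in_und) return false;
    }
    for (int f : var_flow_out[v]) {
      const Flow &fl = flows[f];
      if (fl.in_sel > fl.out_sel + fl.out_und) return false;
      if (fl.out_sel > fl.in_sel + fl.in_und) return false;
    }
    for (int c : var_cover[v]) {
      if (covers[c].sel == 0 && covers[c].und == 0) return false;
    }
    if (val == 1) {
      for (int u : confl[v]) {
        if (state[u] == 1) return false;
        if (state[u] == -1 && !assign(u, 0)) return false;
      }
    }
    return true;
  }

  void undo_to(size_t mark) {
    while (trail.size() > mark) {
      int v = trail.back(); trail.pop_back();
      int val = state[v];
      state[v] = -1;
      und++;
      if (val == 1) cur--;
      for (int f : var_flow_in[v]) { flows[f].in_und++; flows[f].in_sel -= val; }
      for (int f : var_flow_out[v]) { flows[f].out_und++; flows[f].out_sel -= val; }
      for (int c : var_cover[v]) { covers[c].und++; covers[c].sel -= val; }
    }
  }

  bool feasible_now() const {
    for (const Flow &fl : flows) {
      if (fl.in_sel > fl.out_sel + fl.out_und) return false;
      if (fl.out_sel > fl.in_sel + fl.in_und) return false;
    }
    for (const Cover &cv : covers) {
      if (cv.sel == 0 && cv.und == 0) return false;
    }
    return true;
  }

  void search(int pos) {
    nodes++;
    if (cur + und <= best) return;
    int v = -1;
    for (int p = pos; p < n; p++) {
      if (state[order[p]] == -1) { v = order[p]; pos = p; break; }
    }
    if (v == -1) {
      // all decided; counters guarantee feasibility (und == 0 everywhere)
      if (cur > best) { best = cur; best_assign = state; }
      return;
    }
    size_t mark = trail.size();
    if (assign(v, 1)) search(pos + 1);
    undo_to(mark);
    if (cur + und - 1 > best) {
      if (assign(v, 0)) search(pos + 1);
      undo_to(mark);
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".bnb_solve")]]
List bnb_solve(int n, IntegerMatrix conflicts, List flow_in, List flow_out,
               List cover_sets) {
  Solver S;
  S.n = n;
  S.confl.assign(n, {});
  S.var_flow_in.assign(n, {});
  S.var_flow_out.assign(n, {});
  S.var_cover.assign(n, {});
  for (int r = 0; r < conflicts.nrow(); r++) {
    int a = conflicts(r, 0) - 1, b = conflicts(r, 1) - 1;
    S.confl[a].push_back(b);
    S.confl[b].push_back(a);
  }
  int nf = flow_in.size();
  S.flows.resize(nf);
  for (int f = 0; f < nf; f++) {
    IntegerVector iv = flow_in[f], ov = flow_out[f];
    Flow &fl = S.flows[f];
    for (int v : iv) { fl.in.push_back(v - 1); S.var_flow_in[v - 1].push_back(f); }
    for (int v : ov) { fl.out.push_back(v - 1); S.var_flow_out[v - 1].push_back(f); }
    fl.in_sel = fl.out_sel = 0;
    fl.in_und = fl.in.size();
    fl.out_und = fl.out.size();
  }
  int nc = cover_sets.size();
  S.covers.resize(nc);
  for (int c = 0; c < nc; c++) {
    IntegerVector cv = cover_sets[c];
    for (int v : cv) { S.covers[c].mem.push_back(v - 1); S.var_cover[v - 1].push_back(c); }
    S.covers[c].sel = 0;
    S.covers[c].und = S.covers[c].mem.size();
  }
  // most-conflicted variables first: failing early prunes more
  S.order.resize(n);
  for (int i = 0; i < n; i++) S.order[i] = i;
  std::stable_sort(S.order.begin(), S.order.end(), [&](int a, int b) {
    return S.confl[a].size() > S.confl[b].size();
  });
  S.state.assign(n, -1);
  S.cur = 0; S.und = n; S.best = -1; S.nodes = 0;
  S.best_assign.assign(n, 0);
  if (S.feasible_now()) S.search(0);
  if (S.best < 0) stop("infeasible program (coverage constraint unsatisfiable)");
  IntegerVector assign(n);
  for (int i = 0; i < n; i++) assign[i] = S.best_assign[i] == 1 ? 1 : 0;
  return List::create(_["objective"] = S.best, _["assignment"] = assign,
                      _["nodes"] = (double)S.nodes);
}
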