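// Compiled kernels for Boolean-network simulation and mean-field iteration.
// Conventions (shared with the R layer):
//  - regulators of each node are sorted ascending by node index; the FIRST
//    (lowest-index) regulator is the most significant bit of the lookup row;
//  - configurations are encoded as integers with the first enumerated node
//    as the most significant bit.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

namespace {

struct Net {
  int n;
  std::vector<std::vector<int>> regs;  // 0-based regulator indices
  std::vector<std::vector<int>> outs;  // truth-table output bits, length 2^k
};

Net unpack(const List& regs_, const List& outs_) {
  Net net;
  net.n = regs_.size();
  net.regs.resize(net.n);
  net.outs.resize(net.n);
  for (int i = 0; i < net.n; ++i) {
    IntegerVector r = regs_[i];
    IntegerVector o = outs_[i];
    net.regs[i].assign(r.begin(), r.end());
    for (auto& x : net.regs[i]) --x;  // to 0-based
    net.outs[i].assign(o.begin(), o.end());
    if ((size_t)1u << net.regs[i].size() != net.outs[i].size())
      stop("truth table size does not match arity for node %d", i + 1);
  }
  return net;
}

// one synchronous step on a dense 0/1 state vector; pinned handled by caller
inline void step_state(const Net& net, const std::vector<int>& cur,
                       std::vector<int>& nxt, const std::vector<int>& pinned) {
  for (int i = 0; i < net.n; ++i) {
    if (pinned[i] >= 0) { nxt[i] = pinned[i]; continue; }
    const std::vector<int>& r = net.regs[i];
    int row = 0;
    for (size_t j = 0; j < r.size(); ++j) row = (row << 1) | cur[r[j]];
    nxt[i] = net.outs[i][row];
  }
}

// pinned[i] = -1 if free, else 0/1
std::vector<int> pin_vector(int n, const IntegerVector& pin_idx,
                            const IntegerVector& pin_val) {
  std::vector<int> pinned(n, -1);
  for (int j = 0; j < pin_idx.size(); ++j) {
    int i = pin_idx[j] - 1;
    if (i < 0 || i >= n) stop("pinned node index out of range");
    pinned[i] = pin_val[j];
  }
  return pinned;
}

// successor table over the free-node encoding (first free node = MSB)
std::vector<int> successor_table(const Net& net, const std::vector<int>& pinned,
                                 std::vector<int>& free_nodes) {
  free_nodes.clear();
  for (int i = 0; i < net.n; ++i)
    if (pinned[i] < 0) free_nodes.push_back(i);
  int nf = free_nodes.size();
  if (nf > 25) stop("state space too large to enumerate (%d free nodes)", nf);
  size_t nstates = (size_t)1u << nf;
  std::vector<int> state(net.n), nxt(net.n), succ(nstates);
  for (int i = 0; i < net.n; ++i)
    if (pinned[i] >= 0) state[i] = pinned[i];
  for (size_t code = 0; code < nstates; ++code) {
    for (int m = 0; m < nf; ++m)
      state[free_nodes[m]] = (code >> (nf - 1 - m)) & 1u;
    step_state(net, state, nxt, pinned);
    int out = 0;
    for (int m = 0; m < nf; ++m) out = (out << 1) | nxt[free_nodes[m]];
    succ[code] = out;
  }
  return succ;
}

// label every state of a functional graph with its attractor id (1-based);
// returns cycles as vectors of 0-based state codes in cycle order
void label_attractors(const std::vector<int>& succ, std::vector<int>& label,
                      std::vector<std::vector<int>>& cycles) {
  size_t n = succ.size();
  label.assign(n, 0);                 // 0 = unvisited
  std::vector<int> onpath(n, -1);     // position in current path, or -1
  std::vector<int> path;
  for (size_t s = 0; s < n; ++s) {
    if (label[s] != 0) continue;
    path.clear();
    int cur = (int)s;
    while (label[cur] == 0 && onpath[cur] < 0) {
      onpath[cur] = path.size();
      path.push_back(cur);
      cur = succ[cur];
    }
    int id;
    if (label[cur] != 0) {
      id = label[cur];
    } else {
      // new cycle discovered: states from onpath[cur] to end of path
      cycles.emplace_back(path.begin() + onpath[cur], path.end());
      id = (int)cycles.size();
    }
    for (int v : path) { label[v] = id; onpath[v] = -1; }
  }
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_successors(List regs, List outs, IntegerVector pin_idx,
                             IntegerVector pin_val) {
  Net net = unpack(regs, outs);
  std::vector<int> pinned = pin_vector(net.n, pin_idx, pin_val);
  std::vector<int> free_nodes;
  std::vector<int> succ = successor_table(net, pinned, free_nodes);
  return IntegerVector(succ.begin(), succ.end());
}

// [[Rcpp::export]]
List cpp_attractors(IntegerVector succ) {
  std::vector<int> s(succ.begin(), succ.end());
  std::vector<int> label;
  std::vector<std::vector<int>> cycles;
  label_attractors(s, label, cycles);
  List cyc(cycles.size());
  for (size_t i = 0; i < cycles.size(); ++i)
    cyc[i] = IntegerVector(cycles[i].begin(), cycles[i].end());
  return List::create(_["label"] = IntegerVector(label.begin(), label.end()),
                      _["cycles"] = cyc);
}

// [[Rcpp::export]]
NumericMatrix cpp_ibmfa_run(List regs, List outs, NumericVector s0,
                            IntegerVector pin_idx, IntegerVector pin_val,
                            int t_max) {
  Net net = unpack(regs, outs);
  std::vector<int> pinned = pin_vector(net.n, pin_idx, pin_val);
  NumericMatrix traj(t_max + 1, net.n);
  std::vector<double> cur(net.n), nxt(net.n);
  for (int i = 0; i < net.n; ++i)
    cur[i] = pinned[i] >= 0 ? (double)pinned[i] : s0[i];
  for (int i = 0; i < net.n; ++i) traj(0, i) = cur[i];
  for (int t = 1; t <= t_max; ++t) {
    for (int i = 0; i < net.n; ++i) {
      if (pinned[i] >= 0) { nxt[i] = pinned[i]; continue; }
      const std::vector<int>& r = net.regs[i];
      int k = r.size();
      double acc = 0.0;
      int rows = 1 << k;
      for (int row = 0; row < rows; ++row) {
        if (!net.outs[i][row]) continue;
        double p = 1.0;
        for (int j = 0; j < k; ++j) {
          double sj = cur[r[j]];
          p *= ((row >> (k - 1 - j)) & 1) ? sj : 1.0 - sj;
          if (p == 0.0) break;
        }
        acc += p;
      }
      if (acc < 0.0) acc = 0.0;
      if (acc > 1.0) acc = 1.0;
      nxt[i] = acc;
    }
    cur = nxt;
    for (int i = 0; i < net.n; ++i) traj(t, i) = cur[i];
  }
  return traj;
}

// fraction of pin-compatible initial configurations absorbed by the fixed
// point `target_code` (encoded over the free nodes) of the pinned dynamics.
// Successors are computed lazily with a memoised reach/no-reach label per
// state; with `early_exit` the function returns as soon as one
// configuration provably misses the target (useful to test whether a
// candidate seed set is an exact driver).
// [[Rcpp::export]]
double cpp_fraction_to_target(List regs, List outs, IntegerVector pin_idx,
                              IntegerVector pin_val, int target_code,
                              bool early_exit = false) {
  Net net = unpack(regs, outs);
  std::vector<int> pinned = pin_vector(net.n, pin_idx, pin_val);
  std::vector<int> free_nodes;
  for (int i = 0; i < net.n; ++i)
    if (pinned[i] < 0) free_nodes.push_back(i);
  int nf = free_nodes.size();
  if (nf > 25) stop("state space too large to enumerate (%d free nodes)", nf);
  size_t nstates = (size_t)1u << nf;
  if (target_code < 0 || (size_t)target_code >= nstates)
    stop("target code out of range");
  std::vector<int> state(net.n), nxt(net.n);
  for (int i = 0; i < net.n; ++i)
    if (pinned[i] >= 0) state[i] = pinned[i];
  auto successor = [&](int code) {
    for (int m = 0; m < nf; ++m)
      state[free_nodes[m]] = (code >> (nf - 1 - m)) & 1;
    step_state(net, state, nxt, pinned);
    int out = 0;
    for (int m = 0; m < nf; ++m) out = (out << 1) | nxt[free_nodes[m]];
    return out;
  };
  if (successor(target_code) != target_code) return 0.0;
  // label: -1 unknown, 1 reaches target, 0 does not
  std::vector<int8_t> label(nstates, -1);
  std::vector<int> onpath(nstates, -1);
  label[target_code] = 1;
  std::vector<int> path;
  size_t count = 1;
  for (size_t s = 0; s < nstates; ++s) {
    if (label[s] >= 0) continue;
    path.clear();
    int cur = (int)s;
    while (label[cur] < 0 && onpath[cur] < 0) {
      onpath[cur] = path.size();
      path.push_back(cur);
      cur = successor(cur);
    }
    // a freshly found cycle cannot contain the (already labelled) target
    int8_t res = (label[cur] == 1) ? 1 : 0;
    for (int v : path) {
      label[v] = res;
      onpath[v] = -1;
      if (res == 1) ++count;
    }
    // lower bound on the true fraction; only the "== 1" test is meaningful
    if (early_exit && res == 0) return (double)count / (double)nstates;
  }
  return (double)(count) / (double)nstates;
}

// exact synchronous trajectory until the attractor is identified; N <= 62.
// Returns list(transient = #steps before the cycle, cycle = L x N matrix).
// [[Rcpp::export]]
List cpp_walk_attractor(List regs, List outs, IntegerVector pin_idx,
                        IntegerVector pin_val, IntegerVector state0,
                        int max_steps) {
  Net net = unpack(regs, outs);
  if (net.n > 62) stop("walk-based attractor search supports at most 62 nodes");
  std::vector<int> pinned = pin_vector(net.n, pin_idx, pin_val);
  std::vector<int> cur(state0.begin(), state0.end()), nxt(net.n);
  for (int i = 0; i < net.n; ++i)
    if (pinned[i] >= 0) cur[i] = pinned[i];
  auto encode = [&](const std::vector<int>& st) {
    uint64_t c = 0;
    for (int i = 0; i < net.n; ++i) c = (c << 1) | (uint64_t)st[i];
    return c;
  };
  std::unordered_map<uint64_t, int> seen;
  std::vector<std::vector<int>> hist;
  int t = 0;
  while (t <= max_steps) {
    uint64_t code = encode(cur);
    auto it = seen.find(code);
    if (it != seen.end()) {
      int first = it->second;
      int len = t - first;
      IntegerMatrix cyc(len, net.n);
      for (int m = 0; m < len; ++m)
        for (int i = 0; i < net.n; ++i) cyc(m, i) = hist[first + m][i];
      return List::create(_["transient"] = first, _["cycle"] = cyc);
    }
    seen[code] = t;
    hist.push_back(cur);
    step_state(net, cur, nxt, pinned);
    cur = nxt;
    ++t;
  }
  stop("no attractor found within %d steps", max_steps);
}
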