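// Simulated-annealing search over Boolean logic trees (AND/OR nodes,
// possibly complemented leaves) minimising the 2-group misclassification of
// a binary outcome. Self-contained xorshift RNG so that a given seed gives
// bit-identical results on every platform, independent of R's RNG stream.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Xorshift {
  uint64_t s;
  explicit Xorshift(uint64_t seed) : s(seed ? seed * 2685821657736338717ULL
                                            : 0x9E3779B97F4A7C15ULL) {
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int upto(int n) {  // uniform on 0..n-1
    return static_cast<int>(unif() * n) % n;
  }
};

// op: 0 leaf, 1 AND, 2 OR
struct Node { int op, var, neg, left, right; };

struct Tree {
  std::vector<Node> nodes;
  int root;
  int n_leaves() const {
    int k = 0;
    for (size_t i = 0; i < nodes.size(); ++i) if (nodes[i].op == 0) ++k;
    return k;
  }
  std::vector<int> leaves() const {
    std::vector<int> out;
    for (size_t i = 0; i < nodes.size(); ++i)
      if (nodes[i].op == 0) out.push_back(static_cast<int>(i));
    return out;
  }
  std::vector<int> internals() const {
    std::vector<int> out;
    for (size_t i = 0; i < nodes.size(); ++i)
      if (nodes[i].op != 0) out.push_back(static_cast<int>(i));
    return out;
  }
};

void eval_node(const Tree& t, int idx, const std::vector<uint8_t>& X,
               int n, std::vector<uint8_t>& out) {
  const Node& nd = t.nodes[idx];
  if (nd.op == 0) {
    const uint8_t* col = &X[static_cast<size_t>(nd.var) * n];
    if (nd.neg) for (int i = 0; i < n; ++i) out[i] = !col[i];
    else        for (int i = 0; i < n; ++i) out[i] = col[i];
    return;
  }
  std::vector<uint8_t> rhs(n);
  eval_node(t, nd.left, X, n, out);
  eval_node(t, nd.right, X, n, rhs);
  if (nd.op == 1) for (int i = 0; i < n; ++i) out[i] = out[i] && rhs[i];
  else            for (int i = 0; i < n; ++i) out[i] = out[i] || rhs[i];
}

// misclassification when each tree-value group predicts its majority class
int score_tree(const Tree& t, const std::vector<uint8_t>& X, int n,
               const std::vector<int>& y, std::vector<uint8_t>& buf) {
  eval_node(t, t.root, X, n, buf);
  int a = 0, b = 0, c = 0, d = 0;  // (v=1,y=1) (v=1,y=0) (v=0,y=1) (v=0,y=0)
  for (int i = 0; i < n; ++i) {
    if (buf[i]) { if (y[i]) ++a; else ++b; }
    else        { if (y[i]) ++c; else ++d; }
  }
  return std::min(a, b) + std::min(c, d);
}

// rebuild without unreachable nodes (after prune moves)
Tree compact(const Tree& t) {
  Tree out;
  std::vector<int> stack(1, t.root);
  std::vector<int> order;
  while (!stack.empty()) {
    int i = stack.back(); stack.pop_back();
    order.push_back(i);
    if (t.nodes[i].op != 0) {
      stack.push_back(t.nodes[i].left);
      stack.push_back(t.nodes[i].right);
    }
  }
  std::vector<int> remap(t.nodes.size(), -1);
  for (size_t k = 0; k < order.size(); ++k) {
    remap[order[k]] = static_cast<int>(k);
    out.nodes.push_back(t.nodes[order[k]]);
  }
  for (size_t k = 0; k < out.nodes.size(); ++k) {
    if (out.nodes[k].op != 0) {
      out.nodes[k].left = remap[out.nodes[k].left];
      out.nodes[k].right = remap[out.nodes[k].right];
    }
  }
  out.root = remap[t.root];
  return out;
}

Tree propose(const Tree& cur, int p, int max_leaves, Xorshift& rng) {
  Tree t = cur;
  int n_leaves = t.n_leaves();
  bool has_internal = t.nodes.size() > 1;
  // move menu: 0 relabel leaf, 1 complement leaf, 2 flip operator,
  //            3 grow leaf, 4 prune internal node
  std::vector<int> menu;
  menu.push_back(0);
  menu.push_back(1);
  if (has_internal) { menu.push_back(2); menu.push_back(4); }
  if (n_leaves < max_leaves) menu.push_back(3);
  int mv = menu[rng.upto(static_cast<int>(menu.size()))];
  if (mv == 0 || mv == 1 || mv == 3) {
    std::vector<int> lv = t.leaves();
    int tgt = lv[rng.upto(static_cast<int>(lv.size()))];
    if (mv == 0) {
      t.nodes[tgt].var = rng.upto(p);
      t.nodes[tgt].neg = rng.upto(2);
    } else if (mv == 1) {
      t.nodes[tgt].neg = !t.nodes[tgt].neg;
    } else {
      Node old_leaf = t.nodes[tgt];
      Node new_leaf; new_leaf.op = 0; new_leaf.var = rng.upto(p);
      new_leaf.neg = rng.upto(2); new_leaf.left = new_leaf.right = -1;
      t.nodes.push_back(old_leaf);
      t.nodes.push_back(new_leaf);
      int li = static_cast<int>(t.nodes.size()) - 2;
      int ri = li + 1;
      t.nodes[tgt].op = 1 + rng.upto(2);
      t.nodes[tgt].left = li;
      t.nodes[tgt].right = ri;
      t.nodes[tgt].var = -1; t.nodes[tgt].neg = 0;
    }
  } else if (mv == 2) {
    std::vector<int> iv = t.internals();
    int tgt = iv[rng.upto(static_cast<int>(iv.size()))];
    t.nodes[tgt].op = (t.nodes[tgt].op == 1) ? 2 : 1;
  } else {
    std::vector<int> iv = t.internals();
    int tgt = iv[rng.upto(static_cast<int>(iv.size()))];
    int child = rng.upto(2) ? t.nodes[tgt].left : t.nodes[tgt].right;
    t.nodes[tgt] = t.nodes[child];
    // children indices stay valid; unreachable nodes removed by compact()
    t = compact(t);
  }
  return t;
}

}  // namespace

// [[Rcpp::export(name = ".anneal_cpp")]]
List anneal_cpp(IntegerMatrix Xr, IntegerVector yr, int max_leaves,
                double t_start, double cool, int moves_per_temp,
                int max_moves, int stop_no_improve, double t_min,
                double leaf_penalty, int seed) {
  int n = Xr.nrow(), p = Xr.ncol();
  std::vector<uint8_t> X(static_cast<size_t>(n) * p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i)
      X[static_cast<size_t>(j) * n + i] = Xr(i, j) != 0;
  std::vector<int> y(yr.begin(), yr.end());
  Xorshift rng(static_cast<uint64_t>(seed));
  std::vector<uint8_t> buf(n);

  Tree cur;
  Node leaf; leaf.op = 0; leaf.var = rng.upto(p); leaf.neg = rng.upto(2);
  leaf.left = leaf.right = -1;
  cur.nodes.push_back(leaf);
  cur.root = 0;
  double cur_score = score_tree(cur, X, n, y, buf) +
    leaf_penalty * (cur.n_leaves() - 1);
  Tree best = cur;
  double best_score = cur_score;

  // auto start temperature: accept ~90% of typical uphill moves seen on a
  // short random probe walk (90th percentile of the uphill deltas)
  double T = t_start;
  if (T <= 0) {
    std::vector<double> ups;
    Tree probe = cur;
    double probe_score = cur_score;
    for (int k = 0; k < 200; ++k) {
      Tree cand = propose(probe, p, max_leaves, rng);
      double s = score_tree(cand, X, n, y, buf) +
        leaf_penalty * (cand.n_leaves() - 1);
      if (s > probe_score) ups.push_back(s - probe_score);
      probe = cand; probe_score = s;
    }
    double up = 1.0;
    if (!ups.empty()) {
      std::sort(ups.begin(), ups.end());
      up = ups[static_cast<size_t>(0.9 * (ups.size() - 1))];
    }
    T = up / std::log(1.0 / 0.9);
  }

  int moves = 0, since_improve = 0, in_temp = 0;
  while (moves < max_moves && since_improve < stop_no_improve &&
         best_score > 0) {
    Tree cand = propose(cur, p, max_leaves, rng);
    double s = score_tree(cand, X, n, y, buf) +
      leaf_penalty * (cand.n_leaves() - 1);
    ++moves; ++in_temp; ++since_improve;
    double delta = s - cur_score;
    if (delta <= 0 || rng.unif() < std::exp(-delta / T)) {
      cur = cand; cur_score = s;
      if (cur_score < best_score) {
        best = cur; best_score = cur_score; since_improve = 0;
      }
    }
    if (in_temp >= moves_per_temp) {
      in_temp = 0;
      T *= cool;
      if (T < t_min) T = t_min;
    }
  }

  best = compact(best);
  int final_misclass = score_tree(best, X, n, y, buf);
  int m = static_cast<int>(best.nodes.size());
  IntegerMatrix nodes(m, 5);
  colnames(nodes) = CharacterVector::create("op", "var", "neg", "left",
                                            "right");
  for (int i = 0; i < m; ++i) {
    nodes(i, 0) = best.nodes[i].op;
    nodes(i, 1) = best.nodes[i].op == 0 ? best.nodes[i].var + 1 : NA_INTEGER;
    nodes(i, 2) = best.nodes[i].neg;
    nodes(i, 3) = best.nodes[i].op == 0 ? NA_INTEGER : best.nodes[i].left + 1;
    nodes(i, 4) = best.nodes[i].op == 0 ? NA_INTEGER : best.nodes[i].right + 1;
  }
  return List::create(_["nodes"] = nodes, _["root"] = best.root + 1,
                      _["score"] = final_misclass,
                      _["objective"] = best_score, _["n_moves"] = moves);
}
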