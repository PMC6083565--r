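#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Axial coordinates on the triangular (hexagonal) lattice.
// Direction labels 1..6 in counterclockwise cyclic order from (1,0):
//   1 -> ( 1, 0), 2 -> ( 0, 1), 3 -> (-1, 1),
//   4 -> (-1, 0), 5 -> ( 0,-1), 6 -> ( 1,-1).
static const int DQ[6] = { 1, 0, -1, -1, 0, 1 };
static const int DR[6] = { 0, 1,  1,  0, -1, -1 };

// [[Rcpp::export]]
IntegerMatrix decode_dirs_cpp(IntegerVector dirs) {
  int d = dirs.size(), n = d + 1;
  IntegerMatrix out(n, 2);
  int q = 0, r = 0;
  out(0, 0) = 0; out(0, 1) = 0;
  for (int k = 0; k < d; ++k) {
    int lab = dirs[k];
    if (lab < 1 || lab > 6)
      stop("direction label out of range {1..6} at step %d", k + 1);
    q += DQ[lab - 1];
    r += DR[lab - 1];
    out(k + 1, 0) = q;
    out(k + 1, 1) = r;
  }
  return out;
}

// Scratch workspace for grid-based evaluation; reused across a batch.
struct FoldGrid {
  int n, side, offset;
  std::vector<int> occ;    // 0 = empty, else 1-based residue index
  std::vector<int> mult;   // occupancy multiplicity (collision counting)
  std::vector<int> used;   // touched cells, for cheap reset
  std::vector<int> qs, rs;

  explicit FoldGrid(int n_) : n(n_) {
    side = 2 * n + 3;
    offset = n + 1;
    occ.assign((size_t)side * side, 0);
    mult.assign((size_t)side * side, 0);
    used.reserve(n);
    qs.resize(n); rs.resize(n);
  }
  inline int cell(int q, int r) const {
    return (q + offset) * side + (r + offset);
  }
  inline void reset() {
    for (size_t i = 0; i < used.size(); ++i) {
      occ[used[i]] = 0;
      mult[used[i]] = 0;
    }
    used.clear();
  }
};

// Core single-conformation evaluation.
// Fills fitness (= -contacts when self-avoiding, +collision pairs otherwise),
// contact count and collision-pair count. Returns true when self-avoiding.
static bool eval_core(const int* dirs, int d, const int* is_h, FoldGrid& g,
                      double& fitness, int& contacts, int& collisions) {
  int n = d + 1;
  int q = 0, r = 0;
  g.qs[0] = 0; g.rs[0] = 0;
  for (int k = 0; k < d; ++k) {
    int lab = dirs[k];
    q += DQ[lab - 1];
    r += DR[lab - 1];
    g.qs[k + 1] = q;
    g.rs[k + 1] = r;
  }
  collisions = 0;
  for (int i = 0; i < n; ++i) {
    int c = g.cell(g.qs[i], g.rs[i]);
    if (g.mult[c] == 0) g.used.push_back(c);
    collisions += g.mult[c];
    g.mult[c] += 1;
    g.occ[c] = i + 1;           // last occupant; unique when self-avoiding
  }
  contacts = 0;
  bool valid = (collisions == 0);
  if (valid) {
    for (int i = 0; i < n; ++i) {
      if (!is_h[i]) continue;
      for (int m = 0; m < 6; ++m) {
        int c = g.cell(g.qs[i] + DQ[m], g.rs[i] + DR[m]);
        int j = g.occ[c];       // 1-based or 0
        if (j > i + 2 && is_h[j - 1]) ++contacts;  // j - i >= 2, counted once
      }
    }
    fitness = -(double)contacts;
  } else {
    fitness = (double)collisions;
  }
  g.reset();
  return valid;
}

// [[Rcpp::export]]
List eval_dirs_cpp(IntegerVector dirs, LogicalVector is_h) {
  int d = dirs.size();
  if (is_h.size() != d + 1)
    stop("sequence length (%d) must be one more than the number of directions (%d)",
         (int)is_h.size(), d);
  for (int k = 0; k < d; ++k)
    if (dirs[k] < 1 || dirs[k] > 6)
      stop("direction label out of range {1..6} at step %d", k + 1);
  FoldGrid g(d + 1);
  std::vector<int> h(is_h.begin(), is_h.end());
  double fit; int contacts, collisions;
  bool valid = eval_core(INTEGER(dirs), d, h.data(), g, fit, contacts, collisions);
  return List::create(
    _["fitness"] = fit,
    _["valid"] = valid,
    _["contacts"] = contacts,
    _["collisions"] = collisions);
}

// [[Rcpp::export]]
NumericVector fitness_batch_cpp(IntegerMatrix dirs, LogicalVector is_h) {
  int nr = dirs.nrow(), d = dirs.ncol();
  if (is_h.size() != d + 1)
    stop("sequence length must be one more than the number of directions");
  FoldGrid g(d + 1);
  std::vector<int> h(is_h.begin(), is_h.end());
  std::vector<int> row(d);
  NumericVector out(nr);
  for (int i = 0; i < nr; ++i) {
    for (int k = 0; k < d; ++k) {
      int lab = dirs(i, k);
      if (lab < 1 || lab > 6)
        stop("direction label out of range {1..6} at row %d, step %d", i + 1, k + 1);
      row[k] = lab;
    }
    double fit; int contacts, collisions;
    eval_core(row.data(), d, h.data(), g, fit, contacts, collisions);
    out[i] = fit;
  }
  return out;
}

// H-H contact pairs (1-based, i < j, j - i >= 2) of a self-avoiding embedding.
// [[Rcpp::export]]
IntegerMatrix contact_pairs_cpp(IntegerMatrix coords, LogicalVector is_h) {
  int n = coords.nrow();
  if (is_h.size() != n) stop("coordinate rows must match sequence length");
  std::vector<std::pair<int,int> > pairs;
  for (int i = 0; i < n; ++i) {
    if (!is_h[i]) continue;
    for (int j = i + 2; j < n; ++j) {
      if (!is_h[j]) continue;
      int dq = coords(j, 0) - coords(i, 0);
      int dr = coords(j, 1) - coords(i, 1);
      for (int m = 0; m < 6; ++m)
        if (dq == DQ[m] && dr == DR[m]) { pairs.push_back(std::make_pair(i + 1, j + 1)); break; }
    }
  }
  IntegerMatrix out((int)pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    out(k, 0) = pairs[k].first;
    out(k, 1) = pairs[k].second;
  }
  return out;
}

// Sequential greedy re-optimization of single direction labels.
// Positions are visited in the given order; each is replaced by the label
// (out of 1..6) minimizing full-chain fitness. Incumbent kept on ties;
// among non-incumbent ties the smallest label wins.
// [[Rcpp::export]]
IntegerVector greedy_sweep_cpp(IntegerVector dirs, LogicalVector is_h,
                               IntegerVector positions) {
  int d = dirs.size();
  if (is_h.size() != d + 1)
    stop("sequence length must be one more than the number of directions");
  IntegerVector cur = clone(dirs);
  FoldGrid g(d + 1);
  std::vector<int> h(is_h.begin(), is_h.end());
  double fit; int contacts, collisions;
  for (int p = 0; p < positions.size(); ++p) {
    int pos = positions[p];
    if (pos < 1 || pos > d) stop("position %d out of range 1..%d", pos, d);
    int incumbent = cur[pos - 1];
    eval_core(INTEGER(cur), d, h.data(), g, fit, contacts, collisions);
    double best_fit = fit;
    int best_lab = incumbent;
    for (int lab = 1; lab <= 6; ++lab) {
      if (lab == incumbent) continue;
      cur[pos - 1] = lab;
      eval_core(INTEGER(cur), d, h.data(), g, fit, contacts, collisions);
      if (fit < best_fit) { best_fit = fit; best_lab = lab; }
    }
    cur[pos - 1] = best_lab;
  }
  return cur;
}

// ---------------------------------------------------------------------------
// Exhaustive enumeration of self-avoiding walks (depth-first, occupancy grid,
// incremental contact counting). With symmetry_fix the first step is pinned
// to label 1 and the first off-axis step to {2, 3}, exploiting the 12
// point-group isometries of the lattice.
// ---------------------------------------------------------------------------

struct EnumState {
  int n, side, offset;
  std::vector<int> occ;     // 0 empty, else 1-based residue index
  std::vector<int> is_h;
  std::vector<int> dirs, best_dirs;
  std::vector<int> qs, rs;
  int contacts, best_contacts;
  double walks, nodes;
  bool symmetry_fix, count_only, track_all;
  std::vector< std::vector<int> > all_walks;   // only when track_all

  inline int cell(int q, int r) const { return (q + offset) * side + (r + offset); }
};

static void enum_dfs(EnumState& s, int k, int q, int r) {
  // residues 1..k placed (k >= 1); extend with residue k+1
  if (k == s.n) {
    s.walks += 1;
    if (!s.count_only && s.contacts > s.best_contacts) {
      s.best_contacts = s.contacts;
      s.best_dirs = s.dirs;
    }
    if (s.track_all) s.all_walks.push_back(s.dirs);
    return;
  }
  bool off_axis_seen = false;
  if (s.symmetry_fix) {
    for (int i = 0; i < k - 1; ++i)
      if (s.dirs[i] != 1 && s.dirs[i] != 4) { off_axis_seen = true; break; }
  }
  for (int lab = 1; lab <= 6; ++lab) {
    if (s.symmetry_fix) {
      if (k == 1 && lab != 1) continue;            // first step pinned
      if (k > 1 && !off_axis_seen && lab > 4) continue;  // first turn upward
    }
    int nq = q + DQ[lab - 1], nr = r + DR[lab - 1];
    int c = s.cell(nq, nr);
    if (s.occ[c] != 0) continue;
    s.nodes += 1;
    int add = 0;
    if (!s.count_only && s.is_h[k]) {              // residue k+1 is 0-based k
      for (int m = 0; m < 6; ++m) {
        int j = s.occ[s.cell(nq + DQ[m], nr + DR[m])];
        if (j != 0 && j <= k - 1 && s.is_h[j - 1]) ++add;  // |i - j| >= 2
      }
    }
    s.occ[c] = k + 1;
    s.dirs[k - 1] = lab;
    s.contacts += add;
    enum_dfs(s, k + 1, nq, nr);
    s.contacts -= add;
    s.occ[c] = 0;
  }
  s.dirs[k - 1] = 0;
}

static void enum_init(EnumState& s, int n) {
  s.n = n;
  s.side = 2 * n + 3;
  s.offset = n + 1;
  s.occ.assign((size_t)s.side * s.side, 0);
  s.dirs.assign(n > 1 ? n - 1 : 0, 0);
  s.contacts = 0;
  s.best_contacts = -1;
  s.walks = 0;
  s.nodes = 0;
  s.track_all = false;
}

// [[Rcpp::export]]
List enumerate_min_energy_cpp(LogicalVector is_h, bool symmetry_fix) {
  int n = is_h.size();
  if (n < 1) stop("empty sequence");
  EnumState s;
  enum_init(s, n);
  s.is_h.assign(is_h.begin(), is_h.end());
  s.symmetry_fix = symmetry_fix;
  s.count_only = false;
  if (n == 1) {
    return List::create(_["min_energy"] = 0, _["argmin"] = IntegerVector(0),
                        _["walks_visited"] = 1.0, _["nodes"] = 0.0);
  }
  s.occ[s.cell(0, 0)] = 1;
  s.best_dirs.assign(n - 1, 1);   // fallback: straight chain (always valid)
  s.best_contacts = -1;
  enum_dfs(s, 1, 0, 0);
  return List::create(
    _["min_energy"] = -s.best_contacts,
    _["argmin"] = IntegerVector(s.best_dirs.begin(), s.best_dirs.end()),
    _["walks_visited"] = s.walks,
    _["nodes"] = s.nodes);
}

// [[Rcpp::export]]
double count_saws_cpp(int steps, bool symmetry_fix) {
  if (steps < 0) stop("steps must be non-negative");
  if (steps == 0) return 1.0;
  EnumState s;
  enum_init(s, steps + 1);
  s.is_h.assign(steps + 1, 0);
  s.symmetry_fix = symmetry_fix;
  s.count_only = true;
  s.occ[s.cell(0, 0)] = 1;
  enum_dfs(s, 1, 0, 0);
  return s.walks;
}

// All self-avoiding walks of a given length as direction rows (testing aid;
// only sensible for very small step counts).
// [[Rcpp::export]]
IntegerMatrix list_saws_cpp(int steps, bool symmetry_fix) {
  if (steps < 1) stop("steps must be positive");
  EnumState s;
  enum_init(s, steps + 1);
  s.is_h.assign(steps + 1, 0);
  s.symmetry_fix = symmetry_fix;
  s.count_only = true;
  s.track_all = true;
  s.occ[s.cell(0, 0)] = 1;
  enum_dfs(s, 1, 0, 0);
  IntegerMatrix out((int)s.all_walks.size(), steps);
  for (size_t i = 0; i < s.all_walks.size(); ++i)
    for (int k = 0; k < steps; ++k)
      out(i, k) = s.all_walks[i][k];
  return out;
}
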