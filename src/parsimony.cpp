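// Core parsimony engine: bitmask Fitch scoring, component-based branch
// swapping (NNI/SPR/TBR) with random-addition starts, branch-and-bound /
// exhaustive enumeration, per-character refinement-minimum scoring of
// multifurcating trees, and most-parsimonious-reconstruction edge machinery
// used for zero-minimum-branch collapsing and synapomorphy mapping.
//
// Conventions: tips are 0..n-1 (row order of the mask matrix), internal
// nodes n..2n-3.  A cell mask has bit s set iff state s is in the cell's
// state set; missing cells arrive already resolved to the full observed
// state set of their character.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <array>
#include <set>
#include <algorithm>
using namespace Rcpp;

typedef uint32_t mask_t;
static const int BIG = 1 << 28;

// deterministic splitmix64 stream; avoids any dependence on platform RNGs
struct RNG {
  uint64_t state;
  explicit RNG(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  int below(int m) { return (int)(next() % (uint64_t)m); }
};

struct Data {
  int n, nChar;
  std::vector<mask_t> m;  // tip-major: m[tip*nChar + c]
};

static Data make_data(const IntegerMatrix& masks) {
  Data D;
  D.n = masks.nrow();
  D.nChar = masks.ncol();
  D.m.resize((size_t)D.n * D.nChar);
  for (int i = 0; i < D.n; ++i)
    for (int c = 0; c < D.nChar; ++c) {
      int v = masks(i, c);
      if (v <= 0) stop("internal: empty cell mask");
      D.m[(size_t)i * D.nChar + c] = (mask_t)v;
    }
  return D;
}

// ---------------------------------------------------------------------------
// unrooted tree with degree-3 internal nodes
// ---------------------------------------------------------------------------
struct Tree {
  int n;
  std::vector<std::array<int, 3>> nb;  // -1 = empty slot
  explicit Tree(int n_) : n(n_), nb(std::max(2 * n_ - 2, n_ + 1)) {
    for (auto& a : nb) a = {{-1, -1, -1}};
  }
  void addnb(int a, int b) {
    for (int k = 0; k < 3; ++k) if (nb[a][k] < 0) { nb[a][k] = b; return; }
    stop("internal: node degree overflow");
  }
  void delnb(int a, int b) {
    for (int k = 0; k < 3; ++k) if (nb[a][k] == b) { nb[a][k] = -1; return; }
    stop("internal: edge not found");
  }
  void link(int a, int b) { addnb(a, b); addnb(b, a); }
  void cut(int a, int b) { delnb(a, b); delnb(b, a); }
  int degree(int a) const {
    int d = 0;
    for (int k = 0; k < 3; ++k) if (nb[a][k] >= 0) ++d;
    return d;
  }
};

static void suppress_node(Tree& T, int w) {  // w must have degree 2
  int x = -1, y = -1;
  for (int k = 0; k < 3; ++k)
    if (T.nb[w][k] >= 0) { if (x < 0) x = T.nb[w][k]; else y = T.nb[w][k]; }
  T.cut(w, x); T.cut(w, y); T.link(x, y);
}

static void insert_node(Tree& T, int w, int a, int b) {
  T.cut(a, b); T.link(a, w); T.link(w, b);
}

// ---------------------------------------------------------------------------
// Fitch scoring machinery
// ---------------------------------------------------------------------------
struct Work {
  std::vector<mask_t> down, up;
  std::vector<int> parent, post, stack, nodes;
};

// Post-order orientation of the component containing `root`, excluding the
// neighbour `forbid` (-1 = none).  Fills W.parent / W.post (post includes
// `root` last).
static void orient(const Tree& T, int root, int forbid, Work& W) {
  W.parent.assign(T.nb.size(), -9);
  W.post.clear();
  W.stack.clear();
  W.stack.push_back(root);
  W.parent[root] = forbid;  // may be -1
  std::vector<int>& pre = W.nodes;
  pre.clear();
  while (!W.stack.empty()) {
    int v = W.stack.back(); W.stack.pop_back();
    pre.push_back(v);
    for (int k = 0; k < 3; ++k) {
      int w = T.nb[v][k];
      if (w >= 0 && w != W.parent[v]) { W.parent[w] = v; W.stack.push_back(w); }
    }
  }
  W.post.assign(pre.rbegin(), pre.rend());
}

// Fitch down-pass over the oriented component; returns total unions.
// down sets indexed [node*nChar + c].
static long down_pass(const Tree& T, const Data& D, Work& W, int* perChar) {
  const int nc = D.nChar;
  if ((int)W.down.size() < (int)T.nb.size() * nc)
    W.down.assign((size_t)T.nb.size() * nc, 0);
  long tot = 0;
  std::vector<char> seen(T.nb.size(), 0);
  for (int v : W.post) {
    mask_t* dv = &W.down[(size_t)v * nc];
    if (v < T.n && T.degree(v) <= 1) {  // tip
      const mask_t* mv = &D.m[(size_t)v * nc];
      bool has_child = false;
      for (int k = 0; k < 3; ++k) {
        int w = T.nb[v][k];
        if (w >= 0 && w != W.parent[v]) has_child = true;
      }
      if (!has_child) { std::copy(mv, mv + nc, dv); continue; }
    }
    bool first = true;
    for (int k = 0; k < 3; ++k) {
      int w = T.nb[v][k];
      if (w < 0 || w == W.parent[v]) continue;
      const mask_t* dw = &W.down[(size_t)w * nc];
      if (first) { std::copy(dw, dw + nc, dv); first = false; continue; }
      for (int c = 0; c < nc; ++c) {
        mask_t in = dv[c] & dw[c];
        if (in) dv[c] = in;
        else { dv[c] |= dw[c]; ++tot; if (perChar) ++perChar[c]; }
      }
    }
    (void)seen;
  }
  return tot;
}

// total Fitch length of the (binary) tree containing tip `startTip`
static long tree_length(const Tree& T, const Data& D, Work& W, int startTip,
                        int* perChar = nullptr) {
  if (perChar) std::fill(perChar, perChar + D.nChar, 0);
  int c0 = T.nb[startTip][0];
  if (c0 < 0) stop("internal: isolated tip");
  orient(T, c0, startTip, W);
  long tot = down_pass(T, D, W, perChar);
  const mask_t* r = &W.down[(size_t)c0 * D.nChar];
  const mask_t* m0 = &D.m[(size_t)startTip * D.nChar];
  for (int c = 0; c < D.nChar; ++c)
    if (!(r[c] & m0[c])) { ++tot; if (perChar) ++perChar[c]; }
  return tot;
}

// Per-edge "virtual root" state sets of a component (used by RAS and TBR):
// for every edge, the Fitch set of a root subdividing that edge; plus the
// component's unrooted length.
struct CompSets {
  std::vector<int> eu, ev;       // edges (parent, child) in the orientation
  std::vector<mask_t> eset;      // [edge*nChar + c]
  std::vector<mask_t> tipset;    // single-tip component
  int single = -1;
  long len = 0;
};

static inline void fset(const mask_t* a, const mask_t* b, mask_t* out, int nc) {
  for (int c = 0; c < nc; ++c) {
    mask_t in = a[c] & b[c];
    out[c] = in ? in : (a[c] | b[c]);
  }
}

static void comp_sets(const Tree& T, const Data& D, Work& W, int member,
                      CompSets& CS) {
  const int nc = D.nChar;
  // find a tip of the component (degree <= 1 node)
  CS.single = -1; CS.eu.clear(); CS.ev.clear();
  if (T.degree(member) == 0) {
    CS.single = member;
    CS.tipset.assign(&D.m[(size_t)member * nc], &D.m[(size_t)member * nc] + nc);
    CS.len = 0;
    return;
  }
  orient(T, member, -1, W);
  int rootTip = -1;
  for (int v : W.post) if (T.degree(v) == 1) { rootTip = v; break; }
  if (rootTip < 0) stop("internal: component without tips");
  int c0 = T.nb[rootTip][0];
  if (c0 < 0 || T.degree(rootTip) != 1) stop("internal: bad component root");
  if (W.parent[c0] == -9) stop("internal: orientation failure");
  orient(T, c0, rootTip, W);
  CS.len = down_pass(T, D, W, nullptr);
  const mask_t* m0 = &D.m[(size_t)rootTip * nc];
  {
    const mask_t* r = &W.down[(size_t)c0 * nc];
    for (int c = 0; c < nc; ++c) if (!(r[c] & m0[c])) ++CS.len;
  }
  // up sets
  if ((int)W.up.size() < (int)T.nb.size() * nc)
    W.up.assign((size_t)T.nb.size() * nc, 0);
  std::copy(m0, m0 + nc, &W.up[(size_t)c0 * nc]);
  // preorder = reverse postorder
  for (int i = (int)W.post.size() - 1; i >= 0; --i) {
    int u = W.post[i];
    int ch[2], nch = 0;
    for (int k = 0; k < 3; ++k) {
      int w = T.nb[u][k];
      if (w >= 0 && w != W.parent[u]) { if (nch < 2) ch[nch] = w; ++nch; }
    }
    if (nch == 0) continue;
    if (nch != 2 && !(u == c0 && nch <= 2)) {
      if (nch > 2) stop("internal: non-binary component");
    }
    const mask_t* uu = &W.up[(size_t)u * nc];
    if (nch == 1) {
      std::copy(uu, uu + nc, &W.up[(size_t)ch[0] * nc]);
    } else {
      fset(uu, &W.down[(size_t)ch[1] * nc], &W.up[(size_t)ch[0] * nc], nc);
      fset(uu, &W.down[(size_t)ch[0] * nc], &W.up[(size_t)ch[1] * nc], nc);
    }
  }
  // per-edge sets
  int nE = (int)W.post.size() - 1;
  CS.eset.resize((size_t)std::max(nE, 1) * nc);
  int e = 0;
  for (int v : W.post) {
    int p = W.parent[v];
    if (p < 0 || v == c0) { if (v == c0) { /* edge (rootTip,c0) handled below */ } }
  }
  for (int v : W.post) {
    if (v == c0) continue;
    int p = W.parent[v];
    if (p < 0) continue;
    CS.eu.push_back(p); CS.ev.push_back(v);
    fset(&W.down[(size_t)v * nc], &W.up[(size_t)v * nc],
         &CS.eset[(size_t)e * nc], nc);
    ++e;
  }
  // root edge (rootTip, c0)
  CS.eu.push_back(rootTip); CS.ev.push_back(c0);
  if ((int)CS.eset.size() < (e + 1) * nc) CS.eset.resize((size_t)(e + 1) * nc);
  fset(&W.down[(size_t)c0 * nc], m0, &CS.eset[(size_t)e * nc], nc);
}

// ---------------------------------------------------------------------------
// branch swapping
// ---------------------------------------------------------------------------
struct Move {
  int kind = 0;              // 0 = bisection move, 1 = NNI swap
  int cu = -1, cv = -1;      // bisected edge (cu side A, cv side B)
  int au = -1, av = -1;      // reattachment edge in A (if supA)
  int bu = -1, bv = -1;      // reattachment edge in B (if supB)
  bool supA = false, supB = false;
  int nu = -1, nv = -1, na = -1, nb2 = -1;  // NNI: swap (nu,na) with (nv,nb2)
};

static void apply_move(Tree& T, const Move& m) {
  if (m.kind == 1) {
    T.cut(m.nu, m.na); T.cut(m.nv, m.nb2);
    T.link(m.nu, m.nb2); T.link(m.nv, m.na);
    return;
  }
  T.cut(m.cu, m.cv);
  if (m.supA) { suppress_node(T, m.cu); insert_node(T, m.cu, m.au, m.av); }
  if (m.supB) { suppress_node(T, m.cv); insert_node(T, m.cv, m.bu, m.bv); }
  T.link(m.cu, m.cv);
}

static void list_edges(const Tree& T, std::vector<std::pair<int, int>>& E) {
  E.clear();
  for (int a = 0; a < (int)T.nb.size(); ++a)
    for (int k = 0; k < 3; ++k) {
      int b = T.nb[a][k];
      if (b > a) E.emplace_back(a, b);
    }
}

// Evaluate all moves of the given neighbourhood.  Returns the best length
// found; fills *bestMove.  If equalTo >= 0, collects every move whose
// resulting length equals `equalTo` into eq.
static long scan_moves(const Tree& T, const Data& D, Work& W, int swap,
                       long equalTo, std::vector<Move>* eq, Move* bestMove) {
  const int nc = D.nChar;
  long best = -1;
  std::vector<std::pair<int, int>> E;
  list_edges(T, E);
  CompSets A, B;
  Tree Tw(T.n);

  auto consider = [&](const Move& m, long L) {
    if (best < 0 || L < best) { best = L; if (bestMove) *bestMove = m; }
    if (eq && L == equalTo && (long)eq->size() < 200000) eq->push_back(m);
  };

  if (swap == 0) {  // NNI
    Tree Tc(T.n);
    for (auto& e : E) {
      int u = e.first, v = e.second;
      if (u < T.n || v < T.n) continue;  // internal edges only
      int a1 = -1, b1 = -1, b2 = -1;
      for (int k = 0; k < 3; ++k)
        if (T.nb[u][k] >= 0 && T.nb[u][k] != v) { a1 = T.nb[u][k]; break; }
      for (int k = 0; k < 3; ++k) {
        int w = T.nb[v][k];
        if (w >= 0 && w != u) { if (b1 < 0) b1 = w; else b2 = w; }
      }
      for (int bsel = 0; bsel < 2; ++bsel) {
        Move m; m.kind = 1; m.nu = u; m.nv = v; m.na = a1;
        m.nb2 = bsel ? b2 : b1;
        Tc = T;
        apply_move(Tc, m);
        long L = tree_length(Tc, D, W, 0);
        consider(m, L);
      }
    }
    return best;
  }

  // SPR / TBR via bisections
  for (auto& e : E) {
    int u = e.first, v = e.second;
    for (int dir = 0; dir < (swap == 1 ? 2 : 1); ++dir) {
      int cu = dir == 0 ? u : v;  // side A (reattachment edges enumerated here)
      int cv = dir == 0 ? v : u;  // side B
      bool supA = cu >= T.n;
      bool supB = (swap == 2) && cv >= T.n;
      if (swap == 1 && !supA) continue;  // pruning a tip covered by dir swap
      Tw = T;
      Tw.cut(cu, cv);
      int memberA = cu, memberB = cv;
      if (supA) {
        int x = -1;
        for (int k = 0; k < 3; ++k) if (Tw.nb[cu][k] >= 0) { x = Tw.nb[cu][k]; break; }
        suppress_node(Tw, cu);
        memberA = x;
      }
      if (supB) {
        int x = -1;
        for (int k = 0; k < 3; ++k) if (Tw.nb[cv][k] >= 0) { x = Tw.nb[cv][k]; break; }
        suppress_node(Tw, cv);
        memberB = x;
      }
      comp_sets(Tw, D, W, memberA, A);
      if (supB) {
        comp_sets(Tw, D, W, memberB, B);
      } else {
        // B stays rooted at its stub cv: down sets from cv
        B.single = -1; B.eu.clear(); B.ev.clear();
        if (Tw.degree(cv) == 0) {
          B.single = cv; B.len = 0;
          B.tipset.assign(&D.m[(size_t)cv * nc], &D.m[(size_t)cv * nc] + nc);
        } else {
          orient(Tw, cv, -1, W);
          B.len = down_pass(Tw, D, W, nullptr);
          B.tipset.assign(&W.down[(size_t)cv * nc], &W.down[(size_t)cv * nc] + nc);
          B.single = cv;  // attach directly at cv
        }
      }
      int nA = A.single >= 0 ? 1 : (int)A.eu.size();
      int nB = B.single >= 0 ? 1 : (int)B.eu.size();
      if (A.single >= 0 && !supA && nB > 0 && B.single >= 0 && !supB)
        continue;  // two bare nodes: cannot reconnect differently
      for (int ia = 0; ia < nA; ++ia) {
        const mask_t* ra = A.single >= 0 ? A.tipset.data()
                                         : &A.eset[(size_t)ia * nc];
        for (int ib = 0; ib < nB; ++ib) {
          const mask_t* rb = B.single >= 0 ? B.tipset.data()
                                           : &B.eset[(size_t)ib * nc];
          long L = A.len + B.len;
          for (int c = 0; c < nc; ++c) if (!(ra[c] & rb[c])) ++L;
          Move m;
          m.cu = cu; m.cv = cv; m.supA = supA; m.supB = supB;
          if (A.single < 0) { m.au = A.eu[ia]; m.av = A.ev[ia]; }
          if (B.single < 0) { m.bu = B.eu[ib]; m.bv = B.ev[ib]; }
          if (supA && A.single >= 0) stop("internal: suppressed singleton");
          consider(m, L);
        }
      }
    }
  }
  return best;
}

static long climb(Tree& T, const Data& D, Work& W, int swap) {
  long cur = tree_length(T, D, W, 0);
  for (;;) {
    Move bm;
    long b = scan_moves(T, D, W, swap, -1, nullptr, &bm);
    if (b >= 0 && b < cur) { apply_move(T, bm); cur = b; }
    else return cur;
  }
}

// ---------------------------------------------------------------------------
// random addition sequence
// ---------------------------------------------------------------------------
static Tree ras_tree(const Data& D, RNG& rng) {
  int n = D.n, nc = D.nChar;
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  for (int i = n - 1; i > 0; --i) std::swap(perm[i], perm[rng.below(i + 1)]);
  Tree T(n);
  int w0 = n;
  T.link(w0, perm[0]); T.link(w0, perm[1]); T.link(w0, perm[2]);
  Work W;
  CompSets CS;
  std::vector<int> ties;
  int nextInternal = n + 1;
  for (int k = 3; k < n; ++k) {
    int t = perm[k];
    comp_sets(T, D, W, perm[0], CS);
    const mask_t* mt = &D.m[(size_t)t * nc];
    long best = -1;
    ties.clear();
    int nE = (int)CS.eu.size();
    for (int e = 0; e < nE; ++e) {
      const mask_t* r = &CS.eset[(size_t)e * nc];
      long L = CS.len;
      for (int c = 0; c < nc; ++c) if (!(r[c] & mt[c])) ++L;
      if (best < 0 || L < best) { best = L; ties.clear(); ties.push_back(e); }
      else if (L == best) ties.push_back(e);
    }
    int e = ties[rng.below((int)ties.size())];
    int w = nextInternal++;
    insert_node(T, w, CS.eu[e], CS.ev[e]);
    T.link(w, t);
  }
  return T;
}

// ---------------------------------------------------------------------------
// canonical split-set form (for duplicate topologies)
// ---------------------------------------------------------------------------
static std::vector<uint64_t> canon_splits(const Tree& T, Work& W) {
  int n = T.n;
  int words = (n + 63) / 64;
  int c0 = T.nb[0][0];
  orient(T, c0, 0, W);
  std::vector<uint64_t> below((size_t)T.nb.size() * words, 0);
  std::vector<std::vector<uint64_t>> splits;
  for (int v : W.post) {
    uint64_t* bv = &below[(size_t)v * words];
    if (v < n) { bv[v / 64] |= (1ULL << (v % 64)); continue; }
    int ntips = 0;
    for (int k = 0; k < 3; ++k) {
      int w = T.nb[v][k];
      if (w < 0 || w == W.parent[v]) continue;
      const uint64_t* bw = &below[(size_t)w * words];
      for (int q = 0; q < words; ++q) bv[q] |= bw[q];
    }
    for (int q = 0; q < words; ++q) ntips += __builtin_popcountll(bv[q]);
    if (ntips >= 2 && ntips <= n - 2)
      splits.emplace_back(bv, bv + words);
  }
  std::sort(splits.begin(), splits.end());
  std::vector<uint64_t> flat;
  flat.reserve(splits.size() * words);
  for (auto& s : splits) flat.insert(flat.end(), s.begin(), s.end());
  return flat;
}

// ---------------------------------------------------------------------------
// conversions
// ---------------------------------------------------------------------------
static IntegerMatrix tree_to_edge(const Tree& T) {
  int n = T.n;
  int root = T.nb[0][0];
  int nNode = 0;
  for (int v = n; v < (int)T.nb.size(); ++v) if (T.degree(v) > 0) ++nNode;
  IntegerMatrix edge(n + nNode - 1, 2);
  std::vector<int> id(T.nb.size(), -1);
  int nextId = n + 2;  // root gets n+1
  id[root] = n + 1;
  std::vector<std::pair<int, int>> st;  // (node, parent)
  st.emplace_back(root, -1);
  int row = 0;
  // iterative preorder
  std::vector<std::pair<int, int>> stack2;
  stack2.emplace_back(root, -1);
  while (!stack2.empty()) {
    auto pr = stack2.back(); stack2.pop_back();
    int v = pr.first, p = pr.second;
    if (v != root) {
      if (v >= n && id[v] < 0) id[v] = nextId++;
      int vid = v < n ? v + 1 : id[v];
      edge(row, 0) = id[p] >= 0 ? id[p] : p + 1;
      edge(row, 1) = vid;
      ++row;
    }
    for (int k = 2; k >= 0; --k) {
      int w = T.nb[v][k];
      if (w >= 0 && w != p) stack2.emplace_back(w, v);
    }
  }
  if (row != edge.nrow()) stop("internal: edge emission mismatch");
  return edge;
}

// ---------------------------------------------------------------------------
// exported: heuristic search
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_heuristic_search")]]
List cpp_heuristic_search(IntegerMatrix masks, int nrep, int swap,
                          double seed, int maxtrees, int patience,
                          bool expand) {
  Data D = make_data(masks);
  if (D.n < 4) stop("need at least 4 taxa");
  RNG rng((uint64_t)seed);
  Work W;
  long best = -1;
  std::vector<Tree> pool;
  std::set<std::vector<uint64_t>> seen;
  std::vector<int> log;
  bool hitcap = false;
  int sinceImprove = 0;

  for (int rep = 0; rep < nrep; ++rep) {
    if (patience > 0 && sinceImprove >= patience) break;
    Tree T = ras_tree(D, rng);
    long L = climb(T, D, W, swap);
    log.push_back((int)L);
    if (best < 0 || L < best) {
      best = L; pool.clear(); seen.clear();
      seen.insert(canon_splits(T, W));
      pool.push_back(T);
      sinceImprove = 0;
    } else if (L == best) {
      ++sinceImprove;
      auto cs = canon_splits(T, W);
      if (!seen.count(cs)) {
        if ((int)pool.size() < maxtrees) { seen.insert(cs); pool.push_back(T); }
        else hitcap = true;
      }
    } else ++sinceImprove;
    Rcpp::checkUserInterrupt();
  }

  if (expand) {
    size_t idx = 0;
    std::vector<Move> eq;
    while (idx < pool.size()) {
      eq.clear();
      Move bm;
      long b = scan_moves(pool[idx], D, W, swap, best, &eq, &bm);
      if (b >= 0 && b < best) {
        Tree Tn = pool[idx];
        apply_move(Tn, bm);
        long L2 = climb(Tn, D, W, swap);
        best = L2;
        pool.clear(); seen.clear();
        seen.insert(canon_splits(Tn, W));
        pool.push_back(Tn);
        idx = 0;
        continue;
      }
      for (auto& m : eq) {
        Tree Tn = pool[idx];
        apply_move(Tn, m);
        auto cs = canon_splits(Tn, W);
        if (!seen.count(cs)) {
          if ((int)pool.size() < maxtrees) { seen.insert(cs); pool.push_back(Tn); }
          else hitcap = true;
        }
      }
      ++idx;
      Rcpp::checkUserInterrupt();
    }
  }

  List trees((int)pool.size());
  for (int i = 0; i < (int)pool.size(); ++i) trees[i] = tree_to_edge(pool[i]);
  return List::create(_["best_length"] = (double)best, _["trees"] = trees,
                      _["replicate_log"] = wrap(log), _["hit_cap"] = hitcap);
}

// ---------------------------------------------------------------------------
// exported: branch and bound / exhaustive
// ---------------------------------------------------------------------------
struct BnB {
  const Data* D;
  Work W;
  Tree T;
  std::vector<int> ord;
  bool prune;
  std::vector<int> mfull;
  long best = -1;
  std::vector<IntegerMatrix> coll;
  double nodes = 0, maxNodes;
  int maxHold;
  bool hitcap = false;
  std::vector<int> perChar;

  BnB(const Data* d) : D(d), T(d->n) {}

  long bound() {
    long L = tree_length(T, *D, W, ord[0], perChar.data());
    long b = 0;
    for (int c = 0; c < D->nChar; ++c)
      b += std::max(perChar[c], mfull[c]);
    return prune ? b : L;
  }

  void rec(int k) {
    int n = D->n;
    if (k == n) {
      long L = tree_length(T, *D, W, ord[0]);
      if (best < 0 || L < best) { best = L; coll.clear(); }
      if (L == best) {
        if ((int)coll.size() < maxHold) coll.push_back(tree_to_edge(T));
        else hitcap = true;
      }
      return;
    }
    int t = ord[k], w = n + k - 2;
    std::vector<std::pair<int, int>> E;
    list_edges(T, E);
    for (auto& e : E) {
      insert_node(T, w, e.first, e.second);
      T.link(w, t);
      nodes += 1;
      if (nodes > maxNodes) stop("search space too large; raise max_nodes or use heuristic_search()");
      bool ok = true;
      if (prune && best >= 0) {
        long b = bound();
        if (b > best) ok = false;
      }
      if (ok) rec(k + 1);
      T.cut(w, t);
      T.cut(e.first, w); T.cut(w, e.second);
      T.link(e.first, e.second);
      if (k <= 6) Rcpp::checkUserInterrupt();
    }
  }
};

// [[Rcpp::export(name = ".cpp_bnb")]]
List cpp_bnb(IntegerMatrix masks, IntegerVector order0, bool prune,
             IntegerVector mfull, double maxNodes, int maxHold) {
  Data D = make_data(masks);
  int n = D.n;
  if (n < 4) stop("need at least 4 taxa");
  BnB B(&D);
  B.ord = as<std::vector<int>>(order0);
  B.prune = prune;
  B.mfull = as<std::vector<int>>(mfull);
  B.maxNodes = maxNodes;
  B.maxHold = maxHold;
  B.perChar.resize(D.nChar);
  B.T.link(n, B.ord[0]); B.T.link(n, B.ord[1]); B.T.link(n, B.ord[2]);
  if (prune) {
    // greedy addition gives the initial upper bound
    Tree G(n);
    G.link(n, B.ord[0]); G.link(n, B.ord[1]); G.link(n, B.ord[2]);
    Work W;
    CompSets CS;
    int nextInternal = n + 1;
    for (int k = 3; k < n; ++k) {
      int t = B.ord[k];
      comp_sets(G, D, W, B.ord[0], CS);
      const mask_t* mt = &D.m[(size_t)t * D.nChar];
      long bestL = -1; int bestE = 0;
      for (int e = 0; e < (int)CS.eu.size(); ++e) {
        const mask_t* r = &CS.eset[(size_t)e * D.nChar];
        long L = CS.len;
        for (int c = 0; c < D.nChar; ++c) if (!(r[c] & mt[c])) ++L;
        if (bestL < 0 || L < bestL) { bestL = L; bestE = e; }
      }
      int w = nextInternal++;
      insert_node(G, w, CS.eu[bestE], CS.ev[bestE]);
      G.link(w, t);
    }
    B.best = tree_length(G, D, B.W, B.ord[0]);
  }
  B.rec(3);
  List trees((int)B.coll.size());
  for (int i = 0; i < (int)B.coll.size(); ++i) trees[i] = B.coll[i];
  return List::create(_["best_length"] = (double)B.best, _["trees"] = trees,
                      _["nodes"] = B.nodes, _["hit_cap"] = B.hitcap);
}

// ---------------------------------------------------------------------------
// exported: Fitch score of a binary tree given as an ape post-order edge
// matrix (root may be trifurcating, i.e. the standard unrooted encoding)
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_fitch_edge")]]
List cpp_fitch_edge(IntegerMatrix edge, int nTip, IntegerMatrix masks) {
  Data D = make_data(masks);
  int nr = edge.nrow();
  int maxid = 0;
  for (int i = 0; i < nr; ++i)
    maxid = std::max(maxid, std::max(edge(i, 0), edge(i, 1)));
  std::vector<mask_t> set((size_t)maxid * D.nChar, 0);
  std::vector<int> nch(maxid, 0);
  IntegerVector s(D.nChar, 0);
  long tot = 0;
  int root = edge(nr - 1, 0);
  for (int i = 0; i < nTip; ++i)
    std::copy(&D.m[(size_t)i * D.nChar], &D.m[(size_t)i * D.nChar] + D.nChar,
              &set[(size_t)i * D.nChar]);
  for (int i = 0; i < nr; ++i) {
    int p = edge(i, 0) - 1, c = edge(i, 1) - 1;
    mask_t* sp = &set[(size_t)p * D.nChar];
    const mask_t* sc = &set[(size_t)c * D.nChar];
    if (nch[p] == 0) {
      std::copy(sc, sc + D.nChar, sp);
    } else {
      if (nch[p] >= 2 && p + 1 != root)
        stop("tree has polytomies; use the refinement-aware scorer");
      if (nch[p] >= 3) stop("root polytomy of degree > 3");
      for (int ch = 0; ch < D.nChar; ++ch) {
        mask_t in = sp[ch] & sc[ch];
        if (in) sp[ch] = in;
        else { sp[ch] |= sc[ch]; ++tot; ++s[ch]; }
      }
    }
    ++nch[p];
  }
  return List::create(_["total"] = (double)tot, _["s"] = s);
}

// ---------------------------------------------------------------------------
// exported: per-character minimum length over binary refinements of a
// (possibly multifurcating) tree.  Exact subset-DP at each polytomy; each
// character is minimised independently.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_refine_score")]]
List cpp_refine_score(IntegerMatrix edge, int nTip, IntegerMatrix masks,
                      int maxdeg, bool refine = true) {
  Data D = make_data(masks);
  int nr = edge.nrow();
  int maxid = 0;
  for (int i = 0; i < nr; ++i)
    maxid = std::max(maxid, std::max(edge(i, 0), edge(i, 1)));
  std::vector<std::vector<int>> kids(maxid);
  std::vector<char> isChild(maxid, 0);
  for (int i = 0; i < nr; ++i) {
    kids[edge(i, 0) - 1].push_back(edge(i, 1) - 1);
    isChild[edge(i, 1) - 1] = 1;
  }
  int root = -1;
  for (int i = 0; i < nr; ++i)
    if (!isChild[edge(i, 0) - 1]) { root = edge(i, 0) - 1; break; }
  if (root < 0) stop("cannot locate root");
  // postorder over nodes
  std::vector<int> post, stck{root};
  while (!stck.empty()) {
    int v = stck.back(); stck.pop_back();
    post.push_back(v);
    for (int w : kids[v]) stck.push_back(w);
  }
  std::reverse(post.begin(), post.end());

  IntegerVector s(D.nChar, 0);
  long tot = 0;
  for (int c = 0; c < D.nChar; ++c) {
    mask_t uni = 0;
    for (int i = 0; i < nTip; ++i) uni |= D.m[(size_t)i * D.nChar + c];
    std::vector<int> statesv;
    for (int b = 0; b < 31; ++b) if (uni & (1u << b)) statesv.push_back(b);
    int k = (int)statesv.size();
    if (k <= 1) continue;
    std::vector<std::vector<int>> C(maxid);
    for (int v : post) {
      int m = (int)kids[v].size();
      if (m == 0) {
        mask_t mv = D.m[(size_t)v * D.nChar + c];
        C[v].resize(k);
        for (int i = 0; i < k; ++i)
          C[v][i] = (mv & (1u << statesv[i])) ? 0 : BIG;
        continue;
      }
      if (m == 1) {
        const std::vector<int>& cc = C[kids[v][0]];
        int mn = *std::min_element(cc.begin(), cc.end());
        C[v].resize(k);
        for (int i = 0; i < k; ++i) C[v][i] = std::min(cc[i], mn + 1);
        continue;
      }
      if (!refine) {
        // hard polytomy: plain multifurcating Sankoff at this node
        std::vector<int> acc(k, 0);
        for (int ci = 0; ci < m; ++ci) {
          const std::vector<int>& x = C[kids[v][ci]];
          int mn = *std::min_element(x.begin(), x.end());
          for (int q = 0; q < k; ++q)
            acc[q] = std::min(acc[q] + std::min(x[q], mn + 1), BIG);
        }
        C[v] = acc;
        continue;
      }
      if (m > maxdeg)
        stop("polytomy of degree %d exceeds the refinement scorer limit (%d)",
             m, maxdeg);
      int full = (1 << m) - 1;
      std::vector<std::vector<int>> E(full + 1), F(full + 1);
      for (int i = 0; i < m; ++i) {
        E[1 << i] = C[kids[v][i]];
        const std::vector<int>& x = E[1 << i];
        int mn = *std::min_element(x.begin(), x.end());
        F[1 << i].resize(k);
        for (int q = 0; q < k; ++q)
          F[1 << i][q] = std::min(x[q], std::min(mn + 1, BIG));
      }
      for (int sub = 1; sub <= full; ++sub) {
        if (__builtin_popcount(sub) < 2) continue;
        int low = sub & (-sub);
        std::vector<int> bestv(k, BIG);
        for (int s1 = (sub - 1) & sub; s1; s1 = (s1 - 1) & sub) {
          if (!(s1 & low)) continue;
          int s2 = sub ^ s1;
          const std::vector<int>& f1 = F[s1];
          const std::vector<int>& f2 = F[s2];
          for (int q = 0; q < k; ++q) {
            int val = f1[q] + f2[q];
            if (val < bestv[q]) bestv[q] = val;
          }
        }
        E[sub] = bestv;
        int mn = *std::min_element(bestv.begin(), bestv.end());
        F[sub].resize(k);
        for (int q = 0; q < k; ++q)
          F[sub][q] = std::min(bestv[q], mn + 1);
      }
      C[v] = E[full];
    }
    int mc = *std::min_element(C[root].begin(), C[root].end());
    s[c] = mc;
    tot += mc;
  }
  return List::create(_["total"] = (double)tot, _["s"] = s);
}

// ---------------------------------------------------------------------------
// exported: per-edge most-parsimonious-reconstruction machinery on a binary
// tree.  For each edge and character, the set of (parent-state, child-state)
// pairs realised by at least one most-parsimonious reconstruction, encoded
// as bit a*6+b (state digits <= 5).  Also reports, per edge, whether every
// character admits a reconstruction with zero change on that edge (the
// zero-minimum-branch collapse test).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_mpr_pairs")]]
List cpp_mpr_pairs(IntegerMatrix edge, int nTip, IntegerMatrix masks) {
  Data D = make_data(masks);
  int nr = edge.nrow();
  int maxid = 0;
  for (int i = 0; i < nr; ++i)
    maxid = std::max(maxid, std::max(edge(i, 0), edge(i, 1)));
  std::vector<std::vector<int>> kids(maxid);
  std::vector<int> par(maxid, -1), erow(maxid, -1);
  for (int i = 0; i < nr; ++i) {
    int p = edge(i, 0) - 1, c = edge(i, 1) - 1;
    kids[p].push_back(c);
    par[c] = p;
    erow[c] = i;
  }
  int root = -1;
  for (int i = 0; i < nr; ++i) if (par[edge(i, 0) - 1] < 0) { root = edge(i, 0) - 1; break; }
  for (int v = 0; v < maxid; ++v) {
    int m = (int)kids[v].size();
    if (m != 0 && m != 2 && !(v == root && m == 3))
      stop("reconstruction machinery requires a binary tree");
  }
  std::vector<int> post, stck{root};
  while (!stck.empty()) {
    int v = stck.back(); stck.pop_back();
    post.push_back(v);
    for (int w : kids[v]) stck.push_back(w);
  }
  std::reverse(post.begin(), post.end());
  std::vector<int> pre(post.rbegin(), post.rend());

  IntegerMatrix pairs(nr, D.nChar);
  LogicalMatrix zero(nr, D.nChar);
  IntegerVector charmin(D.nChar);

  for (int c = 0; c < D.nChar; ++c) {
    mask_t uni = 0;
    for (int i = 0; i < nTip; ++i) uni |= D.m[(size_t)i * D.nChar + c];
    std::vector<int> st;
    for (int b = 0; b < 31; ++b) if (uni & (1u << b)) st.push_back(b);
    int k = (int)st.size();
    if (k == 0) stop("character with no states");
    for (int q = 0; q < k; ++q)
      if (st[q] > 4) stop("state digits above 4 are not supported here");
    std::vector<std::vector<int>> Dn(maxid), Bp(maxid);
    auto fmin = [&](const std::vector<int>& x) {
      int mn = *std::min_element(x.begin(), x.end());
      std::vector<int> out(k);
      for (int q = 0; q < k; ++q) out[q] = std::min(x[q], mn + 1);
      return out;
    };
    for (int v : post) {
      if (kids[v].empty()) {
        mask_t mv = D.m[(size_t)v * D.nChar + c];
        Dn[v].resize(k);
        for (int q = 0; q < k; ++q)
          Dn[v][q] = (mv & (1u << st[q])) ? 0 : BIG;
      } else {
        std::vector<int> acc(k, 0);
        for (int w : kids[v]) {
          std::vector<int> f = fmin(Dn[w]);
          for (int q = 0; q < k; ++q) acc[q] = std::min(acc[q] + f[q], BIG);
        }
        Dn[v] = acc;
      }
    }
    int cmin = *std::min_element(Dn[root].begin(), Dn[root].end());
    charmin[c] += cmin;
    for (int v : pre) {
      if (kids[v].empty()) continue;
      std::vector<int> BU;
      if (v == root) BU.assign(k, 0);
      else BU = fmin(Bp[v]);
      for (int w : kids[v]) {
        std::vector<int> acc = BU;
        for (int w2 : kids[v]) {
          if (w2 == w) continue;
          std::vector<int> f = fmin(Dn[w2]);
          for (int q = 0; q < k; ++q) acc[q] = std::min(acc[q] + f[q], BIG);
        }
        Bp[w] = acc;
      }
    }
    for (int v = 0; v < maxid; ++v) {
      if (par[v] < 0) continue;
      int row = erow[v];
      int pb = 0;
      bool z = false;
      for (int qa = 0; qa < k; ++qa) {
        long ba = Bp[v][qa];
        if (ba >= BIG) continue;
        for (int qb = 0; qb < k; ++qb) {
          long tot2 = ba + (qa != qb ? 1 : 0) + Dn[v][qb];
          if (tot2 == cmin) {
            pb |= 1 << (st[qa] * 6 + st[qb]);
            if (qa == qb) z = true;
          }
        }
      }
      pairs(row, c) = pb;
      zero(row, c) = z;
    }
  }
  LogicalVector collapse_ok(nr);
  for (int i = 0; i < nr; ++i) {
    bool all0 = true;
    for (int c = 0; c < D.nChar; ++c) if (!zero(i, c)) { all0 = false; break; }
    collapse_ok[i] = all0;
  }
  return List::create(_["pairs"] = pairs, _["collapse_ok"] = collapse_ok,
                      _["charmin"] = charmin);
}

// ---------------------------------------------------------------------------
// exported: plain Fitch length of an internal Tree given a starting RAS,
// used by tests to re-score search output through an independent path is
// done in R; this helper exists for the RAS itself.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_ras_tree")]]
IntegerMatrix cpp_ras_tree(IntegerMatrix masks, double seed) {
  Data D = make_data(masks);
  if (D.n < 4) stop("need at least 4 taxa");
  RNG rng((uint64_t)seed);
  Tree T = ras_tree(D, rng);
  return tree_to_edge(T);
}
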