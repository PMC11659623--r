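// Connected maximum-common-substructure search and subgraph match counting on
// small molecular graphs. Graphs arrive from R as list(elem = atomic numbers,
// bonds = n x 3 integer matrix [i, j, order], 1-based).
#include <Rcpp.h>
#include <set>
#include <map>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Graph {
  int n;
  std::vector<int> elem;
  // adjacency: for each atom, (neighbor, bond order)
  std::vector<std::vector<std::pair<int, int> > > adj;

  int bondOrder(int a, int b) const {
    for (size_t k = 0; k < adj[a].size(); ++k)
      if (adj[a][k].first == b) return adj[a][k].second;
    return 0;
  }
};

Graph buildGraph(const List& g) {
  Graph G;
  IntegerVector elem = g["elem"];
  IntegerMatrix bonds = g["bonds"];
  G.n = elem.size();
  G.elem.assign(elem.begin(), elem.end());
  G.adj.resize(G.n);
  for (int k = 0; k < bonds.nrow(); ++k) {
    int i = bonds(k, 0) - 1, j = bonds(k, 1) - 1, o = bonds(k, 2);
    G.adj[i].push_back(std::make_pair(j, o));
    G.adj[j].push_back(std::make_pair(i, o));
  }
  return G;
}

struct McsSearch {
  const Graph *A, *B;
  std::vector<int> mapA, mapB;          // -1 = unmapped
  std::vector<char> forbidden;          // A atoms excluded in this subtree
  std::vector<std::pair<int, int> > cur;
  int bestAtoms, bestBonds;
  std::vector<std::pair<int, int> > bestPairs;
  long long budget;

  // count of common bonds among currently mapped pairs
  int commonBonds(const std::vector<std::pair<int, int> >& pairs) const {
    int nb = 0;
    for (size_t p = 0; p < pairs.size(); ++p)
      for (size_t q = p + 1; q < pairs.size(); ++q) {
        int oA = A->bondOrder(pairs[p].first, pairs[q].first);
        if (oA == 0) continue;
        int oB = B->bondOrder(pairs[p].second, pairs[q].second);
        if (oA == oB) ++nb;
      }
    return nb;
  }

  void consider() {
    int na = (int)cur.size();
    if (na < bestAtoms) return;
    int nb = commonBonds(cur);
    if (na > bestAtoms || (na == bestAtoms && nb > bestBonds)) {
      bestAtoms = na;
      bestBonds = nb;
      bestPairs = cur;
    }
  }

  // upper bound: per-element counts of still-available atoms on both sides
  int bound() const {
    std::map<int, int> remA, remB;
    for (int a = 0; a < A->n; ++a)
      if (mapA[a] < 0 && !forbidden[a]) ++remA[A->elem[a]];
    for (int b = 0; b < B->n; ++b)
      if (mapB[b] < 0) ++remB[B->elem[b]];
    int s = 0;
    for (std::map<int, int>::const_iterator it = remA.begin(); it != remA.end(); ++it) {
      std::map<int, int>::const_iterator jt = remB.find(it->first);
      if (jt != remB.end()) s += std::min(it->second, jt->second);
    }
    return s;
  }

  void extend() {
    if (budget-- <= 0) return;
    consider();
    if ((int)cur.size() + bound() < bestAtoms) return;  // allow ties: bond count breaks them

    // frontier: smallest unmapped, unforbidden A atom joinable by a common edge
    int a = -1;
    for (int cand = 0; cand < A->n && a < 0; ++cand) {
      if (mapA[cand] >= 0 || forbidden[cand]) continue;
      for (size_t k = 0; k < A->adj[cand].size(); ++k)
        if (mapA[A->adj[cand][k].first] >= 0) { a = cand; break; }
    }
    if (a < 0) return;  // no extension possible

    // branch 1: map a to each compatible b (joined via a matching edge)
    std::set<int> cands;
    for (size_t k = 0; k < A->adj[a].size(); ++k) {
      int ap = A->adj[a][k].first, o = A->adj[a][k].second;
      if (mapA[ap] < 0) continue;
      int bp = mapA[ap];
      for (size_t m = 0; m < B->adj[bp].size(); ++m) {
        int b = B->adj[bp][m].first;
        if (mapB[b] < 0 && B->adj[bp][m].second == o && B->elem[b] == A->elem[a])
          cands.insert(b);
      }
    }
    for (std::set<int>::const_iterator it = cands.begin(); it != cands.end(); ++it) {
      int b = *it;
      mapA[a] = b; mapB[b] = a; cur.push_back(std::make_pair(a, b));
      extend();
      cur.pop_back(); mapA[a] = -1; mapB[b] = -1;
    }
    // branch 2: exclude a entirely in this subtree
    forbidden[a] = 1;
    extend();
    forbidden[a] = 0;
  }
};

}  // namespace

// Connected MCS between two molecular graphs (atoms compared by element, bonds
// by order). Returns mapped atoms of both graphs and the common bond list
// (indices into graph A, 1-based). Deterministic; `budget` caps the number of
// search-node expansions, keeping the best result found so far.
// [[Rcpp::export]]
List mcs_cpp(List gA, List gB, double budget = 2e5) {
  Graph A = buildGraph(gA), B = buildGraph(gB);
  McsSearch S;
  S.A = &A; S.B = &B;
  S.mapA.assign(A.n, -1);
  S.mapB.assign(B.n, -1);
  S.forbidden.assign(A.n, 0);
  S.bestAtoms = 0; S.bestBonds = -1;
  S.budget = (long long)budget;

  // enumerate by seed pair; seed a0 only explores subgraphs whose smallest
  // A atom is a0 (atoms < a0 are forbidden below it)
  for (int a0 = 0; a0 < A.n; ++a0) {
    if (S.budget <= 0) break;
    if (1 + S.bound() < S.bestAtoms) { S.forbidden[a0] = 1; continue; }
    for (int b0 = 0; b0 < B.n; ++b0) {
      if (B.elem[b0] != A.elem[a0]) continue;
      S.mapA[a0] = b0; S.mapB[b0] = a0;
      S.cur.push_back(std::make_pair(a0, b0));
      S.extend();
      S.cur.pop_back();
      S.mapA[a0] = -1; S.mapB[b0] = -1;
    }
    S.forbidden[a0] = 1;  // later seeds must not reuse a0
  }

  int na = S.bestAtoms;
  IntegerVector atomsA(na), atomsB(na);
  for (int i = 0; i < na; ++i) {
    atomsA[i] = S.bestPairs[i].first + 1;
    atomsB[i] = S.bestPairs[i].second + 1;
  }
  std::vector<int> bi, bj, bo;
  for (int p = 0; p < na; ++p)
    for (int q = p + 1; q < na; ++q) {
      int oA = A.bondOrder(S.bestPairs[p].first, S.bestPairs[q].first);
      if (oA == 0) continue;
      int oB = B.bondOrder(S.bestPairs[p].second, S.bestPairs[q].second);
      if (oA == oB) { bi.push_back(p + 1); bj.push_back(q + 1); bo.push_back(oA); }
    }
  IntegerMatrix bonds(bi.size(), 3);
  for (size_t k = 0; k < bi.size(); ++k) {
    bonds(k, 0) = bi[k]; bonds(k, 1) = bj[k]; bonds(k, 2) = bo[k];
  }
  return List::create(_["n_atoms"] = na, _["atoms_a"] = atomsA,
                      _["atoms_b"] = atomsB, _["bonds"] = bonds,
                      _["exhausted"] = (S.budget <= 0));
}

namespace {

struct Matcher {
  const Graph *P, *M;
  std::vector<int> order;   // pattern atoms in connected DFS order
  std::vector<int> mapP;    // pattern -> molecule
  std::vector<char> usedM;
  std::set<std::vector<int> > found;  // distinct matched atom sets
  bool stopAtFirst, hit;

  void run() {
    hit = false;
    mapP.assign(P->n, -1);
    usedM.assign(M->n, 0);
    place(0);
  }

  void place(size_t depth) {
    if (hit && stopAtFirst) return;
    if (depth == order.size()) {
      hit = true;
      if (!stopAtFirst) {
        std::vector<int> s;
        for (int p = 0; p < P->n; ++p) s.push_back(mapP[p]);
        std::sort(s.begin(), s.end());
        found.insert(s);
      }
      return;
    }
    int p = order[depth];
    for (int m = 0; m < M->n; ++m) {
      if (usedM[m] || M->elem[m] != P->elem[p]) continue;
      // every pattern bond from p to an already-placed atom must exist in M
      bool ok = true;
      for (size_t k = 0; k < P->adj[p].size() && ok; ++k) {
        int pp = P->adj[p][k].first;
        if (mapP[pp] < 0) continue;
        if (M->bondOrder(m, mapP[pp]) != P->adj[p][k].second) ok = false;
      }
      if (!ok) continue;
      mapP[p] = m; usedM[m] = 1;
      place(depth + 1);
      mapP[p] = -1; usedM[m] = 0;
      if (hit && stopAtFirst) return;
    }
  }
};

std::vector<int> connectedOrder(const Graph& P) {
  std::vector<int> order;
  std::vector<char> seen(P.n, 0);
  if (P.n == 0) return order;
  order.push_back(0); seen[0] = 1;
  for (size_t i = 0; i < order.size(); ++i) {
    int u = order[i];
    for (size_t k = 0; k < P.adj[u].size(); ++k) {
      int v = P.adj[u][k].first;
      if (!seen[v]) { seen[v] = 1; order.push_back(v); }
    }
  }
  // patterns are connected by construction; any stragglers appended defensively
  for (int v = 0; v < P.n; ++v)
    if (!seen[v]) order.push_back(v);
  return order;
}

}  // namespace

// Number of distinct substructure matches (distinct matched atom sets) of a
// pattern graph in a molecule graph; bonds must match by order, extra molecule
// bonds are allowed (non-induced matching).
// [[Rcpp::export]]
int match_count_cpp(List gP, List gM) {
  Graph P = buildGraph(gP), M = buildGraph(gM);
  if (P.n == 0 || P.n > M.n) return 0;
  Matcher S;
  S.P = &P; S.M = &M;
  S.order = connectedOrder(P);
  S.stopAtFirst = false;
  S.run();
  return (int)S.found.size();
}

// [[Rcpp::export]]
bool has_match_cpp(List gP, List gM) {
  Graph P = buildGraph(gP), M = buildGraph(gM);
  if (P.n == 0 || P.n > M.n) return false;
  Matcher S;
  S.P = &P; S.M = &M;
  S.order = connectedOrder(P);
  S.stopAtFirst = true;
  S.run();
  return S.hit;
}

// Applicability matrix kernel: molecules x patterns, either distinct match
// counts or pattern atom count on any match (0 when absent).
// [[Rcpp::export]]
NumericMatrix applicability_cpp(List mols, List pats, bool count_mode) {
  int nm = mols.size(), np = pats.size();
  std::vector<Graph> M(nm), P(np);
  for (int i = 0; i < nm; ++i) M[i] = buildGraph(mols[i]);
  for (int j = 0; j < np; ++j) P[j] = buildGraph(pats[j]);
  NumericMatrix out(nm, np);
  for (int j = 0; j < np; ++j) {
    std::vector<int> ord = connectedOrder(P[j]);
    for (int i = 0; i < nm; ++i) {
      if (P[j].n == 0 || P[j].n > M[i].n) { out(i, j) = 0; continue; }
      Matcher S;
      S.P = &P[j]; S.M = &M[i];
      S.order = ord;
      S.stopAtFirst = !count_mode;
      S.run();
      if (count_mode) out(i, j) = (double)S.found.size();
      else out(i, j) = S.hit ? (double)P[j].n : 0.0;
    }
  }
  return out;
}
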