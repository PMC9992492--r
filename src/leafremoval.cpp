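// Leaf-removal engines for the LCC-constrained minimum input problem.
//
// Three engines share the same machinery:
//  * cpp_mlr      - Karp-Sipser matching leaf removal on the bipartite
//                   representation B alone (random-link fallback);
//  * cpp_dslr     - generalized leaf removal for a minimal dominating set of
//                   a directed graph alone (highest-degree fallback);
//  * cpp_coupled  - the coupled scheme: matching rules on B and domination
//                   rules on the accessibility graph G_l with cross-updates,
//                   constrained so every step is locally optimal for both
//                   problems at once.
//
// All randomness (tie-breaking, fallback choices) draws from R's RNG so a
// set.seed() on the R side makes runs reproducible.

#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

namespace {

inline int runif_int(int k) {  // uniform on 0..k-1
  int r = (int)(unif_rand() * k);
  return r >= k ? k - 1 : r;
}

enum MState { FREE = 0, MATCHED = 1, GONE = 2 };
enum Label { UNOBS = 0, OBS = 1, DOM = 2 };

struct Engine {
  int n;
  bool hasB, hasG;

  // bipartite representation B: one edge (u+, v-) per directed link (u -> v)
  std::vector<int> bu, bv;
  std::vector<char> balive;
  std::vector<std::vector<int> > padj, madj;  // live edge ids at v+ / v-
  std::vector<int> bdegP, bdegM;
  long blive;

  // accessibility graph G_l
  std::vector<int> gu, gv;
  std::vector<char> galive;
  std::vector<std::vector<int> > gout, gin;
  std::vector<int> goutDeg, ginDeg;
  long glive;

  std::vector<char> lab;        // UNOBS / OBS / DOM
  std::vector<char> msP, msM;   // match state of v+ / v-
  std::vector<int> matchOfM;    // plus partner of a matched v-, else -1

  std::vector<int> gdeg0;       // total degree in the original G_l

  std::deque<int> qPlus, qIso, qSource, qMinusLeaf, qDS2, qDS3;
  long heuristicSteps;
  long bcore, gcore;            // live edges at the first stall
  bool coreRecorded;
  bool keyOriginal;             // heuristic degree key: original vs live G_l

  Engine(int n_, IntegerVector bfrom, IntegerVector bto, IntegerVector gfrom,
         IntegerVector gto, bool hasB_, bool hasG_)
      : n(n_), hasB(hasB_), hasG(hasG_), blive(0), glive(0),
        heuristicSteps(0), bcore(0), gcore(0), coreRecorded(false),
        keyOriginal(false) {
    lab.assign(n, UNOBS);
    msP.assign(n, FREE);
    msM.assign(n, FREE);
    matchOfM.assign(n, -1);
    if (hasB) {
      int m = bfrom.size();
      bu.resize(m);
      bv.resize(m);
      balive.assign(m, 1);
      padj.assign(n, std::vector<int>());
      madj.assign(n, std::vector<int>());
      bdegP.assign(n, 0);
      bdegM.assign(n, 0);
      for (int e = 0; e < m; ++e) {
        bu[e] = bfrom[e] - 1;
        bv[e] = bto[e] - 1;
        padj[bu[e]].push_back(e);
        madj[bv[e]].push_back(e);
        ++bdegP[bu[e]];
        ++bdegM[bv[e]];
      }
      blive = m;
    }
    if (hasG) {
      int m = gfrom.size();
      gu.resize(m);
      gv.resize(m);
      galive.assign(m, 1);
      gout.assign(n, std::vector<int>());
      gin.assign(n, std::vector<int>());
      goutDeg.assign(n, 0);
      ginDeg.assign(n, 0);
      for (int e = 0; e < m; ++e) {
        gu[e] = gfrom[e] - 1;
        gv[e] = gto[e] - 1;
        gout[gu[e]].push_back(e);
        gin[gv[e]].push_back(e);
        ++goutDeg[gu[e]];
        ++ginDeg[gv[e]];
      }
      glive = m;
    }
    gdeg0.assign(n, 0);
    if (hasG)
      for (int v = 0; v < n; ++v) gdeg0[v] = goutDeg[v] + ginDeg[v];
    for (int v = 0; v < n; ++v) {
      if (hasB) {
        if (bdegP[v] == 1) qPlus.push_back(v);
        if (bdegM[v] == 1) qMinusLeaf.push_back(v);
        if (bdegM[v] == 0) qIso.push_back(v);
      }
      if (hasG && ginDeg[v] == 0) qSource.push_back(v);
    }
  }

  void removeBEdge(int e) {
    if (!balive[e]) return;
    balive[e] = 0;
    --blive;
    int u = bu[e], v = bv[e];
    if (--bdegP[u] == 1) qPlus.push_back(u);
    int dm = --bdegM[v];
    if (dm == 1) qMinusLeaf.push_back(v);
    else if (dm == 0) qIso.push_back(v);
  }

  void clearB(std::vector<int> &lst) {
    for (size_t k = 0; k < lst.size(); ++k) removeBEdge(lst[k]);
    lst.clear();
  }

  void removeGEdge(int e) {
    if (!galive[e]) return;
    galive[e] = 0;
    --glive;
    int u = gu[e], v = gv[e];
    int od = --goutDeg[u];
    if (od == 1) qDS3.push_back(u);
    else if (od == 0) { qDS2.push_back(u); qMinusLeaf.push_back(u); }
    int id = --ginDeg[v];
    if (id == 0) qSource.push_back(v);
    else if (id == 1) qDS2.push_back(v);
  }

  // live edges only ever point at unobserved nodes: observing a node deletes
  // its incoming links
  void observe(int w) {
    if (lab[w] != UNOBS) return;
    lab[w] = OBS;
    for (size_t k = 0; k < gin[w].size(); ++k) removeGEdge(gin[w][k]);
    gin[w].clear();
    qMinusLeaf.push_back(w);
    qDS3.push_back(w);
  }

  void dominate(int v) {
    if (lab[v] == DOM) return;
    lab[v] = DOM;
    if (msM[v] == MATCHED) matchOfM[v] = -1;  // drop the pair: v must be unmatched
    msM[v] = GONE;
    if (hasB) clearB(madj[v]);
    if (hasG) {
      for (size_t k = 0; k < gin[v].size(); ++k) removeGEdge(gin[v][k]);
      gin[v].clear();
      for (size_t k = 0; k < gout[v].size(); ++k) {
        int e = gout[v][k];
        if (galive[e]) observe(gv[e]);  // also deletes the edge e itself
      }
      gout[v].clear();
    }
  }

  void matchEdge(int e) {
    int u = bu[e], v = bv[e];
    msP[u] = MATCHED;
    msM[v] = MATCHED;
    matchOfM[v] = u;
    clearB(padj[u]);
    clearB(madj[v]);
    qDS2.push_back(v);
    qDS3.push_back(v);
  }

  // compacting scan for one live edge id in an adjacency list
  int findLive(std::vector<int> &lst, const std::vector<char> &alive) {
    while (!lst.empty()) {
      int e = lst.back();
      if (alive[e]) return e;
      lst.pop_back();
    }
    return -1;
  }

  int liveCount(std::vector<int> &lst, const std::vector<char> &alive) {
    size_t w = 0;
    for (size_t k = 0; k < lst.size(); ++k)
      if (alive[lst[k]]) lst[w++] = lst[k];
    lst.resize(w);
    return (int)w;
  }

  int gdeg(int v) const {
    return keyOriginal ? gdeg0[v] : goutDeg[v] + ginDeg[v];
  }

  // `coupled` switches the matching-side constraints of the coupled scheme on;
  // off, the M rules are plain Karp-Sipser and the DS rules plain generalized
  // leaf removal.
  void propagate(bool coupled) {
    for (;;) {
      if (hasB && !qPlus.empty()) {
        int u = qPlus.front(); qPlus.pop_front();
        if (msP[u] == FREE && bdegP[u] == 1) {
          int e = findLive(padj[u], balive);
          if (e >= 0) matchEdge(e);
        }
      } else if (hasB && !qIso.empty()) {
        int v = qIso.front(); qIso.pop_front();
        // an isolated, unmatched v- is forced to be an input node
        if (msM[v] == FREE && bdegM[v] == 0) {
          if (hasG) dominate(v);
          else msM[v] = GONE;  // matching alone: v simply stays unmatched
        }
      } else if (hasG && !qSource.empty()) {
        int v = qSource.front(); qSource.pop_front();
        if (lab[v] == UNOBS && ginDeg[v] == 0) dominate(v);  // Rule-DS1
      } else if (hasB && !qMinusLeaf.empty()) {
        int v = qMinusLeaf.front(); qMinusLeaf.pop_front();
        // Rule-M on a minus leaf: only once v cannot become dominating
        bool ok = msM[v] == FREE && bdegM[v] == 1;
        if (ok && coupled) ok = lab[v] == OBS && goutDeg[v] == 0;
        if (ok) {
          int e = findLive(madj[v], balive);
          if (e >= 0) matchEdge(e);
        }
      } else if (hasG && !qDS2.empty()) {
        int v = qDS2.front(); qDS2.pop_front();
        bool ok = lab[v] == UNOBS && ginDeg[v] == 1 && goutDeg[v] == 0;
        if (ok && coupled) ok = msM[v] == MATCHED;
        if (ok) {
          int e = findLive(gin[v], galive);
          if (e >= 0) dominate(gu[e]);  // Rule-DS2: the lone predecessor
        }
      } else if (hasG && !qDS3.empty()) {
        int v = qDS3.front(); qDS3.pop_front();
        bool ok = lab[v] == OBS && goutDeg[v] == 1;
        if (ok && coupled) ok = msM[v] == MATCHED;
        if (ok) {
          int e = findLive(gout[v], galive);
          if (e >= 0) removeGEdge(e);  // Rule-DS3: drop (v, w), w stays unobserved
        }
      } else {
        break;
      }
    }
  }

  void heuristic() {
    ++heuristicSteps;
    if (hasB && blive > 0) {
      // match the minus copy least likely to be needed as a dominating node:
      // minimum live total degree in G_l (ties uniform at random)
      int best = -1, bestKey = -1, ties = 0;
      for (int v = 0; v < n; ++v) {
        if (msM[v] != FREE || bdegM[v] == 0) continue;
        int key = hasG ? gdeg(v) : 0;
        if (best < 0 || key < bestKey) { best = v; bestKey = key; ties = 1; }
        else if (key == bestKey && unif_rand() * (++ties) < 1.0) best = v;
      }
      int cnt = liveCount(madj[best], balive);
      matchEdge(madj[best][runif_int(cnt)]);
    } else if (hasG && glive > 0) {
      // B exhausted: commit the highest-degree node as dominating
      int best = -1, bestKey = -1, ties = 0;
      for (int v = 0; v < n; ++v) {
        if (goutDeg[v] + ginDeg[v] == 0) continue;
        int key = gdeg(v);
        if (key > bestKey) { best = v; bestKey = key; ties = 1; }
        else if (key == bestKey && unif_rand() * (++ties) < 1.0) best = v;
      }
      dominate(best);
    }
  }

  void run(bool coupled, bool finish) {
    propagate(coupled);
    bcore = blive;
    gcore = glive;
    while (finish && (blive > 0 || glive > 0)) {
      heuristic();
      propagate(coupled);
    }
    if (finish && hasG) {
      // no live links left: any still-unobserved node has lost all its
      // in-links and is forced dominating (queues are empty at this point
      // only if every such node was already handled, but be safe)
      for (int v = 0; v < n; ++v)
        if (lab[v] == UNOBS) dominate(v);
    }
  }

  List report() {
    std::vector<int> inputs, mfrom, mto, dom;
    for (int v = 0; v < n; ++v) {
      if (msM[v] != MATCHED) inputs.push_back(v + 1);
      if (lab[v] == DOM) dom.push_back(v + 1);
      if (matchOfM[v] >= 0) {
        mfrom.push_back(matchOfM[v] + 1);
        mto.push_back(v + 1);
      }
    }
    std::vector<int> lbf, lbt, lgf, lgt;  // live edges (diagnostics)
    for (size_t e = 0; e < balive.size(); ++e)
      if (balive[e]) { lbf.push_back(bu[e] + 1); lbt.push_back(bv[e] + 1); }
    for (size_t e = 0; e < galive.size(); ++e)
      if (galive[e]) { lgf.push_back(gu[e] + 1); lgt.push_back(gv[e] + 1); }
    return List::create(
        _["inputs"] = wrap(inputs), _["dominating"] = wrap(dom),
        _["match_from"] = wrap(mfrom), _["match_to"] = wrap(mto),
        _["b_core_edges"] = (double)bcore, _["g_core_edges"] = (double)gcore,
        _["heuristic_steps"] = (double)heuristicSteps,
        _["live_b"] = List::create(wrap(lbf), wrap(lbt)),
        _["live_g"] = List::create(wrap(lgf), wrap(lgt)));
  }
};

}  // namespace

// Coupled leaf removal: original links (bfrom, bto) define B, accessibility
// links (gfrom, gto) define G_l.
// [[Rcpp::export]]
List cpp_coupled(int n, IntegerVector bfrom, IntegerVector bto,
                 IntegerVector gfrom, IntegerVector gto, bool finish,
                 bool key_original = false) {
  Engine eng(n, bfrom, bto, gfrom, gto, true, true);
  eng.keyOriginal = key_original;
  eng.run(true, finish);
  return eng.report();
}

// Pure Karp-Sipser matching leaf removal on B.
// [[Rcpp::export]]
List cpp_mlr(int n, IntegerVector bfrom, IntegerVector bto, bool finish) {
  Engine eng(n, bfrom, bto, IntegerVector(0), IntegerVector(0), true, false);
  eng.propagate(false);
  eng.bcore = eng.blive;
  while (finish && eng.blive > 0) {
    // fallback: put a uniformly random live link into the matching
    ++eng.heuristicSteps;
    std::vector<int> live;
    for (size_t e = 0; e < eng.balive.size(); ++e)
      if (eng.balive[e]) live.push_back((int)e);
    eng.matchEdge(live[runif_int((int)live.size())]);
    eng.propagate(false);
  }
  return eng.report();
}

// Pure dominating-set leaf removal on a directed graph.
// [[Rcpp::export]]
List cpp_dslr(int n, IntegerVector gfrom, IntegerVector gto, bool finish) {
  Engine eng(n, IntegerVector(0), IntegerVector(0), gfrom, gto, false, true);
  eng.run(false, finish);
  return eng.report();
}
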