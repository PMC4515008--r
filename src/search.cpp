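#include <Rcpp.h>
#include <functional>
#include <unordered_map>
#include <unordered_set>
#include "kbloom.h"

using namespace Rcpp;
using gapclosr::CascadeBloom;
using gapclosr::is_acgt;

// One BFS level: node -> the nodes it was reached from one level earlier.
typedef std::unordered_map<std::string, std::vector<std::string> > Level;

static List make_result(const std::string& status,
                        const std::vector<std::string>& paths,
                        int n_paths) {
  return List::create(_["status"] = status, _["paths"] = wrap(paths),
                      _["n_paths"] = n_paths);
}

// Depth-limited bidirectional breadth-first path enumeration between two
// anchor k-mers over the implicit de Bruijn graph held in a cascading Bloom
// filter. Frontiers alternate one level at a time (left first); every walk
// prefix/suffix endpoint is recorded per depth with its predecessors, and
// complete paths are assembled wherever the two search DAGs share a state.
// A path may not visit the same k-mer twice in the same orientation.
//
// status: "ok" (paths returned), "no_path", "length_limit", "branch_limit",
// "too_many_paths".
// [[Rcpp::export]]
List enumerate_paths_cpp(SEXP bp, std::string start, std::string goal,
                         int max_edges, int max_branches, int max_paths) {
  XPtr<CascadeBloom> B(bp);
  const int k = B->k;
  if ((int)start.size() != k || (int)goal.size() != k)
    stop("start/goal must have length k = %d", k);
  for (size_t i = 0; i < start.size(); ++i)
    if (!is_acgt(start[i]) || !is_acgt(goal[i]))
      stop("start/goal must be ACGT-only");
  if (max_branches < 1) stop("max_branches must be >= 1");
  if (max_paths < 1) stop("max_paths must be >= 1");

  if (start == goal) {
    std::vector<std::string> p(1, start);
    return make_result("ok", p, 1);
  }
  std::vector<std::string> none;
  if (max_edges <= 0) return make_result("length_limit", none, 0);

  std::vector<Level> L(1), Rv(1);
  L[0][start] = std::vector<std::string>();
  Rv[0][goal] = std::vector<std::string>();
  std::vector<std::string> fL(1, start), fR(1, goal);
  bool next_left = true, branch_hit = false;
  int dL = 0, dR = 0;
  std::string cand, rcbuf;

  while (dL + dR < max_edges && (!fL.empty() || !fR.empty())) {
    bool do_left;
    if (fL.empty()) {
      do_left = false;
    } else if (fR.empty()) {
      do_left = true;
    } else {
      do_left = next_left;
      next_left = !next_left;
    }
    Level nm;
    const std::vector<std::string>& fr = do_left ? fL : fR;
    for (size_t vi = 0; vi < fr.size(); ++vi) {
      const std::string& v = fr[vi];
      for (int ci = 0; ci < 4; ++ci) {
        const char c = "ACGT"[ci];
        if (do_left)
          cand = v.substr(1) + c;
        else
          cand = std::string(1, c) + v.substr(0, (size_t)k - 1);
        if (B->solid_kmer(cand, rcbuf)) nm[cand].push_back(v);
      }
    }
    std::vector<std::string> nf;
    nf.reserve(nm.size());
    for (Level::const_iterator it = nm.begin(); it != nm.end(); ++it)
      nf.push_back(it->first);
    if (do_left) {
      L.push_back(Level());
      L.back().swap(nm);
      fL.swap(nf);
      ++dL;
    } else {
      Rv.push_back(Level());
      Rv.back().swap(nm);
      fR.swap(nf);
      ++dR;
    }
    if ((long long)fL.size() + (long long)fR.size() > (long long)max_branches) {
      branch_hit = true;
      break;
    }
    Rcpp::checkUserInterrupt();
  }

  if (branch_hit) return make_result("branch_limit", none, 0);
  const bool exhausted = fL.empty() && fR.empty();

  // Forward adjacency of the left DAG for path reconstruction.
  std::vector<Level> childL(L.size());
  for (size_t d = 0; d + 1 < L.size(); ++d)
    for (Level::const_iterator it = L[d + 1].begin(); it != L[d + 1].end(); ++it)
      for (size_t pi = 0; pi < it->second.size(); ++pi)
        childL[d][it->second[pi]].push_back(it->first);

  std::unordered_set<std::string> seen_spellings;
  std::vector<std::string> spellings;
  std::vector<std::string> lpath(1, start), rstack;
  std::unordered_set<std::string> onpath;
  onpath.insert(start);
  long long work = 0;
  const long long WORK_CAP = 20000000LL;
  bool abort_now = false, overflow = false, too_many = false;

  std::function<void(const std::string&, int)> go_right =
      [&](const std::string& v, int dr) {
        if (abort_now) return;
        if (++work > WORK_CAP) {
          overflow = abort_now = true;
          return;
        }
        if (dr == 0) {  // v == goal; emit lpath + rstack
          std::string sp = lpath[0];
          for (size_t i = 1; i < lpath.size(); ++i)
            sp += lpath[i][lpath[i].size() - 1];
          for (size_t i = 0; i < rstack.size(); ++i)
            sp += rstack[i][rstack[i].size() - 1];
          if (seen_spellings.insert(sp).second) {
            spellings.push_back(sp);
            if ((int)spellings.size() > max_paths) too_many = abort_now = true;
          }
          return;
        }
        Level::const_iterator it = Rv[dr].find(v);
        if (it == Rv[dr].end()) return;
        for (size_t ui = 0; ui < it->second.size(); ++ui) {
          const std::string& u = it->second[ui];
          if (onpath.count(u)) continue;
          onpath.insert(u);
          rstack.push_back(u);
          go_right(u, dr - 1);
          rstack.pop_back();
          onpath.erase(u);
          if (abort_now) return;
        }
      };

  std::function<void(const std::string&, int)> go_left =
      [&](const std::string& v, int dl) {
        if (abort_now) return;
        if (++work > WORK_CAP) {
          overflow = abort_now = true;
          return;
        }
        const int maxdr =
            std::min((int)Rv.size() - 1, max_edges - dl);
        for (int dr = 0; dr <= maxdr && !abort_now; ++dr)
          if (Rv[dr].count(v)) go_right(v, dr);
        if (abort_now) return;
        if (dl + 1 < (int)L.size()) {
          Level::const_iterator it = childL[dl].find(v);
          if (it == childL[dl].end()) return;
          for (size_t wi = 0; wi < it->second.size(); ++wi) {
            const std::string& w = it->second[wi];
            if (onpath.count(w)) continue;
            onpath.insert(w);
            lpath.push_back(w);
            go_left(w, dl + 1);
            lpath.pop_back();
            onpath.erase(w);
            if (abort_now) return;
          }
        }
      };

  go_left(start, 0);

  if (too_many)
    return make_result("too_many_paths", none, (int)spellings.size());
  if (overflow)
    return make_result(spellings.empty() ? "branch_limit" : "too_many_paths",
                       none, (int)spellings.size());
  if (!spellings.empty())
    return make_result("ok", spellings, (int)spellings.size());
  return make_result(exhausted ? "no_path" : "length_limit", none, 0);
}
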