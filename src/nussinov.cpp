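// Maximum base-pairing secondary-structure folder (Nussinov recursion) with
// enumeration of co-optimal structures. Used as the built-in desk-scale
// stand-in for a thermodynamic suboptimal folder: all returned structures
// attain the maximal pair count, are non-crossing, respect a minimum hairpin
// loop length, and are deduplicated. Watson-Crick pairs plus G-U wobble;
// ambiguity letters never pair.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <set>
#include <utility>
using namespace Rcpp;

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

typedef std::vector<std::pair<int, int> > PairList;

class Enumerator {
public:
  Enumerator(const std::string &s, const std::vector<std::vector<int> > &M,
             int minloop, size_t cap)
    : s_(s), M_(M), minloop_(minloop), cap_(cap) {}

  std::vector<PairList> run(int i, int j) {
    std::vector<PairList> out;
    if (i >= j || j - i <= minloop_) {
      out.push_back(PairList());
      return out;
    }
    const int target = M_[i][j];
    if (M_[i + 1][j] == target) {            // i left unpaired
      std::vector<PairList> sub = run(i + 1, j);
      for (size_t t = 0; t < sub.size(); ++t) {
        out.push_back(sub[t]);
        if (out.size() >= cap_) return out;
      }
    }
    for (int k = i + minloop_ + 1; k <= j; ++k) {   // i paired with k
      if (!can_pair(s_[i], s_[k])) continue;
      const int inner = (i + 1 <= k - 1 && (k - 1) - (i + 1) > minloop_)
                          ? M_[i + 1][k - 1] : 0;
      const int right = (k + 1 <= j) ? M_[k + 1][j] : 0;
      if (1 + inner + right != target) continue;
      std::vector<PairList> lefts = run(i + 1, k - 1);
      std::vector<PairList> rights = run(k + 1, j);
      for (size_t a = 0; a < lefts.size(); ++a) {
        for (size_t b = 0; b < rights.size(); ++b) {
          PairList comb;
          comb.reserve(lefts[a].size() + rights[b].size() + 1);
          comb.push_back(std::make_pair(i, k));
          comb.insert(comb.end(), lefts[a].begin(), lefts[a].end());
          comb.insert(comb.end(), rights[b].begin(), rights[b].end());
          out.push_back(comb);
          if (out.size() >= cap_) return out;
        }
      }
    }
    return out;
  }

private:
  const std::string &s_;
  const std::vector<std::vector<int> > &M_;
  int minloop_;
  size_t cap_;
};

// [[Rcpp::export(name = ".nussinov_structures")]]
CharacterVector nussinov_structures(std::string seq, int max_structures,
                                    int min_loop) {
  const int L = static_cast<int>(seq.size());
  if (L < 1) stop("empty sequence");
  if (max_structures < 1) stop("max_structures must be >= 1");
  if (min_loop < 0) stop("min_loop must be >= 0");

  std::vector<std::vector<int> > M(L, std::vector<int>(L, 0));
  for (int span = min_loop + 1; span < L; ++span) {
    for (int i = 0; i + span < L; ++i) {
      const int j = i + span;
      int best = M[i + 1][j];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        const int inner = (i + 1 <= k - 1 && (k - 1) - (i + 1) > min_loop)
                            ? M[i + 1][k - 1] : 0;
        const int right = (k + 1 <= j) ? M[k + 1][j] : 0;
        const int v = 1 + inner + right;
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }

  // Enumerate co-optimal tracebacks with headroom for deduplication.
  Enumerator en(seq, M, min_loop,
                static_cast<size_t>(max_structures) * 4 + 4);
  std::vector<PairList> raw = en.run(0, L - 1);

  std::vector<std::string> kept;
  std::set<std::string> seen;
  for (size_t t = 0; t < raw.size(); ++t) {
    std::string db(L, '.');
    for (size_t q = 0; q < raw[t].size(); ++q) {
      db[raw[t][q].first] = '(';
      db[raw[t][q].second] = ')';
    }
    if (seen.insert(db).second) {
      kept.push_back(db);
      if (kept.size() >= static_cast<size_t>(max_structures)) break;
    }
  }
  return wrap(kept);
}
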