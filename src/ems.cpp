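// Core engines for exact (l,d) edit-distance motif search:
//  - three-phase exact-distance-d compact neighborhood generation with
//    duplication-avoiding skip rules 1-9,
//  - motif trie with mutually exclusive subset-labelled edges,
//  - compact radix sort (simultaneous wildcard expansion + sort) and the
//    sorted-array set operations used by the array engine.
// Positions are 1-based throughout, matching R and the trace convention.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

static const char DELC = '-';   // deletion sentinel, kept until emission
static const char STAR = '*';   // wildcard: any symbol of the alphabet

namespace ems {

// ---------------------------------------------------------------------------
// Neighborhood generation
// ---------------------------------------------------------------------------

struct Op { int p; char o; };   // o in {'D','R','I'}, D < R < I at equal p

class Emitter {
public:
  virtual ~Emitter() {}
  virtual void emit(const std::string& motif, int j, int k,
                    const std::vector<Op>& T) = 0;
};

// Enumerates, for one k-mer S[j..j+k-1], all traces with exactly
// delta deletions, beta substitutions and alpha insertions
// (delta+beta+alpha = d, k-delta+alpha = l), phases in that order.
// With rules enabled, the full rule predicate is re-evaluated after each
// appended op; all rule conditions are monotone in the trace set, so pruning
// a partial trace is equivalent to filtering completed traces.
class Generator {
public:
  std::string S;
  int m, l, d;
  bool rules;
  Emitter* out;

  int j, k;
  std::string work;            // k-mer with '-' marking deletions, '*' subs
  std::vector<Op> T;
  std::vector<int> ins;        // insertion counts per point offset 0..k

  Generator(const std::string& S_, int l_, int d_, bool rules_, Emitter* out_)
    : S(S_), m((int)S_.size()), l(l_), d(d_), rules(rules_), out(out_) {}

  bool has(int p, char o) const {
    for (const Op& e : T) if (e.p == p && e.o == o) return true;
    return false;
  }

  // skip rules 1-9; t >= 0 in the run conditions of rules 3 and 8.
  bool ruleFires() const {
    if (j + k <= m && has(j, 'D')) return true;                 // rule 1
    for (const Op& e : T) {
      if (e.o == 'D') {
        if (has(e.p + 1, 'R')) return true;                     // rule 2
        if (has(e.p, 'I')) return true;                         // rule 4
        if (has(e.p + 1, 'I')) return true;                     // rule 5
      } else if (e.o == 'R') {
        if (has(e.p, 'I')) return true;                         // rule 6
      }
    }
    if (j + k <= m) {                                           // rule 3
      for (int t = 0; has(j + t, 'R'); ++t)
        if (has(j + t + 1, 'D')) return true;
    }
    if (j > 1) {
      if (has(j, 'I')) return true;                             // rule 7
      for (int t = 0; has(j + t, 'R'); ++t)                     // rule 8
        if (has(j + t + 1, 'I')) return true;
    }
    if (j + k <= m && has(j + k, 'I')) return true;             // rule 9
    return false;
  }

  void emitNow() {
    std::string res;
    res.reserve((size_t)l);
    for (int off = 0; off < k; ++off) {
      for (int c = 0; c < ins[off]; ++c) res.push_back(STAR);
      if (work[off] != DELC) res.push_back(work[off]);
    }
    for (int c = 0; c < ins[k]; ++c) res.push_back(STAR);
    out->emit(res, j, k, T);
  }

  // insertions: points are "just before position p", p in [j, j+k];
  // p = j+k is the right end; one or more insertions per point allowed.
  void phaseI(int startOff, int a) {
    if (a == 0) { emitNow(); return; }
    for (int off = startOff; off <= k; ++off) {
      T.push_back({j + off, 'I'});
      ins[off]++;
      if (!(rules && ruleFires())) phaseI(off, a - 1);
      ins[off]--;
      T.pop_back();
    }
  }

  void phaseR(int startPos, int b, int a) {
    if (b == 0) { phaseI(0, a); return; }
    for (int p = startPos; p <= j + k - 1; ++p) {
      int off = p - j;
      if (work[off] == DELC) continue;
      char saved = work[off];
      work[off] = STAR;
      T.push_back({p, 'R'});
      if (!(rules && ruleFires())) phaseR(p + 1, b - 1, a);
      T.pop_back();
      work[off] = saved;
    }
  }

  void phaseD(int startPos, int dd, int b, int a) {
    if (dd == 0) { phaseR(j, b, a); return; }
    for (int p = startPos; p <= j + k - 1; ++p) {
      int off = p - j;
      char saved = work[off];
      work[off] = DELC;
      T.push_back({p, 'D'});
      if (!(rules && ruleFires())) phaseD(p + 1, dd - 1, b, a);
      T.pop_back();
      work[off] = saved;
    }
  }

  // admissible (delta, beta, alpha): max(0,q) <= delta <= (d+q)/2,
  // alpha = delta - q, beta = d - 2*delta + q, where q = k - l.
  void runKmer(int jj, int kk) {
    j = jj; k = kk;
    work = S.substr((size_t)(j - 1), (size_t)k);
    ins.assign((size_t)(k + 1), 0);
    int q = k - l;
    int dmin = q > 0 ? q : 0;
    int dmax = (d + q) / 2;        // d + q >= 0 since k >= l - d
    for (int dd = dmin; dd <= dmax; ++dd)
      phaseD(j, dd, d - 2 * dd + q, dd - q);
  }
};

class CollectEmitter : public Emitter {
public:
  std::vector<std::string> motifs;
  void emit(const std::string& motif, int, int, const std::vector<Op>&) {
    motifs.push_back(motif);
  }
};

class StatsEmitter : public Emitter {
public:
  double total = 0;
  std::unordered_map<std::string, int> counts;
  void emit(const std::string& motif, int, int, const std::vector<Op>&) {
    total += 1;
    counts[motif] += 1;
  }
};

class TaggedEmitter : public Emitter {
public:
  std::vector<int> js, ks;
  std::vector<std::string> traces, motifs;
  static int orank(char o) { return o == 'D' ? 0 : (o == 'R' ? 1 : 2); }
  void emit(const std::string& motif, int j, int k, const std::vector<Op>& T) {
    std::vector<Op> s(T);
    std::sort(s.begin(), s.end(), [](const Op& a, const Op& b) {
      return a.p != b.p ? a.p < b.p : orank(a.o) < orank(b.o);
    });
    std::string tr;
    for (size_t i = 0; i < s.size(); ++i) {
      if (i) tr.push_back(',');
      tr += std::to_string(s[i].p);
      tr.push_back(s[i].o);
    }
    js.push_back(j); ks.push_back(k);
    traces.push_back(tr); motifs.push_back(motif);
  }
};

static void runWorkloads(Generator& g, const IntegerVector& j,
                         const IntegerVector& k) {
  if (j.size() != k.size()) stop("j and k must have equal length");
  for (R_xlen_t i = 0; i < j.size(); ++i) {
    if (k[i] < 1 || j[i] < 1 || j[i] + k[i] - 1 > g.m)
      stop("workload (j=%d, k=%d) outside the string", j[i], k[i]);
    if (k[i] < g.l - g.d || k[i] > g.l + g.d)
      stop("k=%d outside [l-d, l+d]", k[i]);
    g.runKmer(j[i], k[i]);
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
}

} // namespace ems

// [[Rcpp::export]]
CharacterVector cpp_gen_motifs(std::string S, IntegerVector j, IntegerVector k,
                               int l, int d, bool rules) {
  ems::CollectEmitter em;
  ems::Generator g(S, l, d, rules, &em);
  ems::runWorkloads(g, j, k);
  return wrap(em.motifs);
}

// [[Rcpp::export]]
List cpp_gen_tagged(std::string S, IntegerVector j, IntegerVector k,
                    int l, int d, bool rules) {
  ems::TaggedEmitter em;
  ems::Generator g(S, l, d, rules, &em);
  ems::runWorkloads(g, j, k);
  return List::create(_["j"] = wrap(em.js), _["k"] = wrap(em.ks),
                      _["trace"] = wrap(em.traces),
                      _["motif"] = wrap(em.motifs));
}

// [[Rcpp::export]]
List cpp_gen_stats(std::string S, IntegerVector j, IntegerVector k,
                   int l, int d, bool rules) {
  ems::StatsEmitter em;
  ems::Generator g(S, l, d, rules, &em);
  ems::runWorkloads(g, j, k);
  std::unordered_map<int, double> hist;
  for (auto& kv : em.counts) hist[kv.second] += 1;
  std::vector<int> mult;
  for (auto& kv : hist) mult.push_back(kv.first);
  std::sort(mult.begin(), mult.end());
  std::vector<double> cnt;
  for (int mres : mult) cnt.push_back(hist[mres]);
  return List::create(_["total"] = em.total,
                      _["distinct"] = (double)em.counts.size(),
                      _["multiplicity"] = wrap(mult),
                      _["count"] = wrap(cnt));
}

// ---------------------------------------------------------------------------
// Lexicographic order by alphabet symbol order
// ---------------------------------------------------------------------------

namespace ems {

struct Rank {
  int r[256];
  int sigma;
  explicit Rank(const std::string& alphabet) {
    sigma = (int)alphabet.size();
    for (int i = 0; i < 256; ++i) r[i] = -1;
    for (int i = 0; i < sigma; ++i) {
      unsigned char c = (unsigned char)alphabet[i];
      if (r[c] >= 0) stop("alphabet has repeated symbols");
      r[c] = i;
    }
  }
  int idx(char c) const {
    int v = r[(unsigned char)c];
    if (v < 0) stop("character '%c' not in alphabet", c);
    return v;
  }
  int cmp(const std::string& a, const std::string& b) const {
    size_t n = a.size() < b.size() ? a.size() : b.size();
    for (size_t i = 0; i < n; ++i) {
      int ra = idx(a[i]), rb = idx(b[i]);
      if (ra != rb) return ra < rb ? -1 : 1;
    }
    if (a.size() == b.size()) return 0;
    return a.size() < b.size() ? -1 : 1;
  }
};

static std::vector<std::string> fromCV(const CharacterVector& x) {
  std::vector<std::string> v;
  v.reserve((size_t)x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) v.push_back(as<std::string>(x[i]));
  return v;
}

} // namespace ems

// ---------------------------------------------------------------------------
// Compact radix sort: l phases, position l down to 1; a wildcard at the
// phase's position increments every symbol's bucket and emits |Sigma| copies
// with the wildcard finalized; stable counting sort per phase makes the full
// pass lexicographic in alphabet order.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector cpp_radix_expand(CharacterVector x, std::string alphabet) {
  if (x.size() == 0) return x;
  ems::Rank rk(alphabet);
  int sigma = rk.sigma;
  std::vector<std::string> cur = ems::fromCV(x);
  int l = (int)cur[0].size();
  for (auto& s : cur) {
    if ((int)s.size() != l) stop("motifs must all have the same length");
    for (char c : s) if (c != STAR) rk.idx(c);
  }
  for (int pos = l - 1; pos >= 0; --pos) {
    std::vector<double> B((size_t)sigma, 0.0);
    for (auto& s : cur) {
      if (s[pos] == STAR) for (int q = 0; q < sigma; ++q) B[q] += 1;
      else B[rk.idx(s[pos])] += 1;
    }
    double tot = 0;
    std::vector<double> C((size_t)sigma, 0.0);
    for (int q = 0; q < sigma; ++q) { C[q] = tot; tot += B[q]; }
    if (tot > 2e8) stop("expansion too large (> 2e8 motifs)");
    std::vector<std::string> T((size_t)tot);
    std::vector<double> off(C);
    for (auto& s : cur) {
      if (s[pos] == STAR) {
        for (int q = 0; q < sigma; ++q) {
          std::string t = s;
          t[pos] = alphabet[(size_t)q];
          T[(size_t)off[q]++] = std::move(t);
        }
      } else {
        T[(size_t)off[rk.idx(s[pos])]++] = s;
      }
    }
    cur.swap(T);
    Rcpp::checkUserInterrupt();
  }
  return wrap(cur);
}

// [[Rcpp::export]]
CharacterVector cpp_dedupe_sorted(CharacterVector x, std::string alphabet) {
  ems::Rank rk(alphabet);
  std::vector<std::string> v = ems::fromCV(x);
  std::vector<std::string> out;
  out.reserve(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    if (i > 0) {
      int c = rk.cmp(v[i - 1], v[i]);
      if (c > 0) stop("contract violation: input to dedupe_sorted is not sorted");
      if (c == 0) continue;
    }
    out.push_back(v[i]);
  }
  return wrap(out);
}

// [[Rcpp::export]]
LogicalVector cpp_is_sorted(CharacterVector x, std::string alphabet,
                            bool strict) {
  ems::Rank rk(alphabet);
  std::vector<std::string> v = ems::fromCV(x);
  for (size_t i = 1; i < v.size(); ++i) {
    int c = rk.cmp(v[i - 1], v[i]);
    if (c > 0 || (strict && c == 0)) return false;
  }
  return true;
}

static void checkStrict(const std::vector<std::string>& v, const ems::Rank& rk,
                        const char* who) {
  for (size_t i = 1; i < v.size(); ++i)
    if (rk.cmp(v[i - 1], v[i]) >= 0)
      stop("contract violation: input to %s must be sorted and duplicate-free",
           who);
}

// [[Rcpp::export]]
CharacterVector cpp_intersect_sorted(CharacterVector a, CharacterVector b,
                                     std::string alphabet) {
  ems::Rank rk(alphabet);
  std::vector<std::string> va = ems::fromCV(a), vb = ems::fromCV(b);
  checkStrict(va, rk, "intersect_sorted");
  checkStrict(vb, rk, "intersect_sorted");
  std::vector<std::string> out;
  size_t i = 0, j = 0;
  while (i < va.size() && j < vb.size()) {
    int c = rk.cmp(va[i], vb[j]);
    if (c == 0) { out.push_back(va[i]); ++i; ++j; }
    else if (c < 0) ++i;
    else ++j;
  }
  return wrap(out);
}

// [[Rcpp::export]]
CharacterVector cpp_union_sorted(CharacterVector a, CharacterVector b,
                                 std::string alphabet) {
  ems::Rank rk(alphabet);
  std::vector<std::string> va = ems::fromCV(a), vb = ems::fromCV(b);
  checkStrict(va, rk, "union_sorted");
  checkStrict(vb, rk, "union_sorted");
  std::vector<std::string> out;
  out.reserve(va.size() + vb.size());
  size_t i = 0, j = 0;
  while (i < va.size() || j < vb.size()) {
    if (i == va.size()) out.push_back(vb[j++]);
    else if (j == vb.size()) out.push_back(va[i++]);
    else {
      int c = rk.cmp(va[i], vb[j]);
      if (c == 0) { out.push_back(va[i]); ++i; ++j; }
      else if (c < 0) out.push_back(va[i++]);
      else out.push_back(vb[j++]);
    }
  }
  return wrap(out);
}

// ---------------------------------------------------------------------------
// Motif trie: edges carry mutually exclusive non-empty subsets of the
// alphabet (bitmasks); a non-empty trie has l+1 levels; the trie stores the
// l-mer s1..sl iff each sj lies in the label of the level-j edge of a path.
// ---------------------------------------------------------------------------

namespace ems {

struct TNode {
  std::vector<std::pair<uint32_t, TNode*>> ch;
};

static void freeNode(TNode* u) {
  for (auto& pr : u->ch) freeNode(pr.second);
  delete u;
}

static TNode* deepCopy(const TNode* u) {
  TNode* v = new TNode();
  v->ch.reserve(u->ch.size());
  for (auto& pr : u->ch) v->ch.push_back({pr.first, deepCopy(pr.second)});
  return v;
}

struct Trie {
  TNode* root;
  int l;
  std::string alphabet;
  uint32_t full;
  Rank rk;
  Trie(int l_, const std::string& a)
    : root(new TNode()), l(l_), alphabet(a), rk(a) {
    if (rk.sigma > 31) stop("alphabet too large for the trie engine (max 31)");
    full = (rk.sigma == 31) ? 0x7fffffffu : ((1u << rk.sigma) - 1u);
  }
  ~Trie() { freeNode(root); }

  // copy-on-split insert of a compact motif
  void insertSuffix(TNode* u, int lev, const std::string& A) {
    if (lev == l) return;
    char a = A[(size_t)lev];
    if (a != STAR) {
      uint32_t bm = 1u << rk.idx(a);
      int found = -1;
      for (size_t i = 0; i < u->ch.size(); ++i)
        if (u->ch[i].first & bm) { found = (int)i; break; }
      if (found >= 0) {
        if (u->ch[found].first == bm) {
          insertSuffix(u->ch[found].second, lev + 1, A);
        } else {
          TNode* v2 = deepCopy(u->ch[(size_t)found].second);
          u->ch[(size_t)found].first &= ~bm;
          u->ch.push_back({bm, v2});
          insertSuffix(v2, lev + 1, A);
        }
      } else {
        TNode* v = new TNode();
        u->ch.push_back({bm, v});
        insertSuffix(v, lev + 1, A);
      }
    } else {
      size_t n0 = u->ch.size();
      uint32_t covered = 0;
      for (size_t i = 0; i < n0; ++i) covered |= u->ch[i].first;
      for (size_t i = 0; i < n0; ++i) insertSuffix(u->ch[i].second, lev + 1, A);
      uint32_t R = full & ~covered;
      if (R) {
        TNode* v = new TNode();
        u->ch.push_back({R, v});
        insertSuffix(v, lev + 1, A);
      }
    }
  }

  // children pair up by label intersection; dead branches pruned eagerly
  TNode* inter(const TNode* a, const TNode* b, int lev) const {
    TNode* w = new TNode();
    if (lev == l) return w;
    for (auto& pa : a->ch) {
      for (auto& pb : b->ch) {
        uint32_t L = pa.first & pb.first;
        if (!L) continue;
        TNode* c = inter(pa.second, pb.second, lev + 1);
        if (lev + 1 == l || !c->ch.empty()) w->ch.push_back({L, c});
        else freeNode(c);
      }
    }
    return w;
  }

  void dfs(const TNode* u, int lev, std::string& buf,
           std::vector<std::string>& out) const {
    if (lev == l) { out.push_back(buf); return; }
    for (int q = 0; q < rk.sigma; ++q) {
      uint32_t bm = 1u << q;
      for (auto& pr : u->ch) {
        if (pr.first & bm) {
          buf.push_back(alphabet[(size_t)q]);
          dfs(pr.second, lev + 1, buf, out);
          buf.pop_back();
          break;    // labels are mutually exclusive: at most one child
        }
      }
    }
  }

  double countLmers(const TNode* u, int lev) const {
    if (lev == l) return 1.0;
    double s = 0;
    for (auto& pr : u->ch) {
      int pc = 0;
      for (uint32_t b = pr.first; b; b &= b - 1) ++pc;
      s += pc * countLmers(pr.second, lev + 1);
    }
    return s;
  }

  bool check(const TNode* u, int lev) const {
    if (lev == l) return u->ch.empty();
    if (lev > 0 || u != root) {
      if (u->ch.empty()) return false;   // all paths must reach level l
    }
    uint32_t seen = 0;
    for (auto& pr : u->ch) {
      if (pr.first == 0 || (pr.first & ~full)) return false;
      if (pr.first & seen) return false; // labels must be mutually exclusive
      seen |= pr.first;
      if (!check(pr.second, lev + 1)) return false;
    }
    return true;
  }

  int nodeCount(const TNode* u) const {
    int n = 1;
    for (auto& pr : u->ch) n += nodeCount(pr.second);
    return n;
  }
};

} // namespace ems

// [[Rcpp::export]]
SEXP cpp_trie_new(int l, std::string alphabet) {
  XPtr<ems::Trie> p(new ems::Trie(l, alphabet), true);
  return p;
}

// [[Rcpp::export]]
void cpp_trie_insert(SEXP ptr, CharacterVector motifs) {
  XPtr<ems::Trie> t(ptr);
  for (R_xlen_t i = 0; i < motifs.size(); ++i) {
    std::string a = as<std::string>(motifs[i]);
    if ((int)a.size() != t->l)
      stop("motif length %d does not match trie depth %d", (int)a.size(), t->l);
    for (char c : a) if (c != STAR) t->rk.idx(c);
    t->insertSuffix(t->root, 0, a);
    if (i % 512 == 0) Rcpp::checkUserInterrupt();
  }
}

// [[Rcpp::export]]
SEXP cpp_trie_intersect(SEXP p1, SEXP p2) {
  XPtr<ems::Trie> a(p1), b(p2);
  if (a->l != b->l || a->alphabet != b->alphabet)
    stop("tries must have the same depth and alphabet");
  ems::Trie* w = new ems::Trie(a->l, a->alphabet);
  ems::freeNode(w->root);
  w->root = a->inter(a->root, b->root, 0);
  XPtr<ems::Trie> p(w, true);
  return p;
}

// [[Rcpp::export]]
CharacterVector cpp_trie_enumerate(SEXP ptr) {
  XPtr<ems::Trie> t(ptr);
  std::vector<std::string> out;
  std::string buf;
  t->dfs(t->root, 0, buf, out);
  return wrap(out);
}

// [[Rcpp::export]]
bool cpp_trie_is_empty(SEXP ptr) {
  XPtr<ems::Trie> t(ptr);
  return t->l > 0 && t->root->ch.empty();
}

// [[Rcpp::export]]
double cpp_trie_count(SEXP ptr) {
  XPtr<ems::Trie> t(ptr);
  return t->countLmers(t->root, 0);
}

// [[Rcpp::export]]
bool cpp_trie_check(SEXP ptr) {
  XPtr<ems::Trie> t(ptr);
  return t->check(t->root, 0);
}

// [[Rcpp::export]]
int cpp_trie_node_count(SEXP ptr) {
  XPtr<ems::Trie> t(ptr);
  return t->nodeCount(t->root);
}

// [[Rcpp::export]]
CharacterVector cpp_trie_root_labels(SEXP ptr) {
  XPtr<ems::Trie> t(ptr);
  std::vector<std::string> out;
  for (auto& pr : t->root->ch) {
    std::string s;
    for (int q = 0; q < t->rk.sigma; ++q)
      if (pr.first & (1u << q)) s.push_back(t->alphabet[(size_t)q]);
    out.push_back(s);
  }
  return wrap(out);
}
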