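// Compact prefix trie over 2-bit encoded reads.
//
// The trie stores each collapsed unary chain as a length (chain_len) only;
// chain characters are recovered from the encoded text through a
// representative read, so the structure itself is O(k) for k reads while the
// text is n log|Sigma| bits.  Nodes carry the interval [r1, r2] of
// lexicographic read ids sharing the root-to-node prefix, plus n_end, the
// number of reads ending exactly at the node (n_end generalises "leaf" so
// that prefix-contained reads are representable when filtering is off).

#include <Rcpp.h>
#include <vector>
#include <array>
using namespace Rcpp;

static inline int base_at(const unsigned char *txt, long long gpos) {
  return (txt[gpos >> 2] >> ((gpos & 3) << 1)) & 3;
}

static int code_of(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}

// ---------------------------------------------------------------- encoding

// [[Rcpp::export]]
List cpp_encode_bases(CharacterVector seqs) {
  long long n = 0;
  int k = seqs.size();
  IntegerVector off(k), len(k);
  for (int i = 0; i < k; ++i) {
    off[i] = (int)n;
    len[i] = LENGTH(STRING_ELT(seqs, i));
    n += len[i];
  }
  if (n > INT_MAX)
    stop("total length exceeds supported maximum (2^31 - 1 bases)");
  RawVector raw((n + 3) / 4);
  std::fill(raw.begin(), raw.end(), 0);
  unsigned char *p = RAW(raw);
  long long g = 0;
  for (int i = 0; i < k; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    for (int j = 0; j < len[i]; ++j, ++g) {
      int c = code_of(s[j]);
      if (c < 0)
        stop("sequence %d contains a non-ACGT character ('%c')", i + 1, s[j]);
      p[g >> 2] |= (unsigned char)(c << ((g & 3) << 1));
    }
  }
  return List::create(_["raw"] = raw, _["offsets"] = off, _["lengths"] = len,
                      _["n"] = (double)n);
}

// [[Rcpp::export]]
CharacterVector cpp_decode_bases(RawVector raw, IntegerVector offsets,
                                 IntegerVector lengths) {
  static const char LUT[4] = {'A', 'C', 'G', 'T'};
  int k = offsets.size();
  CharacterVector out(k);
  const unsigned char *p = RAW(raw);
  std::string buf;
  for (int i = 0; i < k; ++i) {
    buf.assign(lengths[i], 'N');
    for (int j = 0; j < lengths[i]; ++j)
      buf[j] = LUT[base_at(p, (long long)offsets[i] + j)];
    out[i] = buf;
  }
  return out;
}

// ---------------------------------------------------------------- arena

struct Arena {
  std::vector<signed char> label;        // 0..3, -1 for root
  std::vector<int> chain_len, r1, r2, n_end, rep; // rep: 0-based insertion idx
  std::vector<std::array<int, 4>> kids;  // 0-based node index, -1 absent
  std::vector<std::vector<int>> enders;  // 1-based original indices
  long long comparisons = 0;

  int new_node(int lab, int cl) {
    label.push_back((signed char)lab);
    chain_len.push_back(cl);
    r1.push_back(0);
    r2.push_back(0);
    n_end.push_back(0);
    rep.push_back(-1);
    kids.push_back({-1, -1, -1, -1});
    enders.push_back(std::vector<int>());
    return (int)label.size() - 1;
  }
  Arena() { new_node(-1, 0); } // root = 0
};

// Insert read `i` (0-based position in insertion order).  In sorted mode the
// read's id is i+1 and intervals are maintained inline; otherwise intervals
// are left for the DFS relabeling stage.  `orig` is the 1-based original
// (file-order) index recorded in the terminal registry.
static void insert_read(Arena &A, const unsigned char *txt,
                        const int *off, const int *len, int i, int orig,
                        bool sorted) {
  const int id = i + 1;
  const int L = len[i];
  const long long o = off[i];
  int cur = 0, pos = 0;
  for (;;) {
    const int cl = A.chain_len[cur];
    const long long orep = (cur == 0) ? 0 : off[A.rep[cur]];
    int lp = 1;
    while (lp <= cl) {
      if (pos == L) {
        // read exhausted mid-chain: split, upper part becomes terminal
        int v2 = A.new_node(base_at(txt, orep + pos), cl - lp);
        A.kids[v2] = A.kids[cur];
        A.n_end[v2] = A.n_end[cur];
        A.enders[v2] = std::move(A.enders[cur]);
        A.rep[v2] = A.rep[cur];
        if (sorted) { A.r1[v2] = A.r1[cur]; A.r2[v2] = id - 1; }
        A.chain_len[cur] = lp - 1;
        A.kids[cur] = {-1, -1, -1, -1};
        A.kids[cur][(int)A.label[v2]] = v2;
        A.n_end[cur] = 1;
        A.enders[cur].assign(1, orig);
        return;
      }
      A.comparisons++;
      int c = base_at(txt, o + pos);
      int cc = base_at(txt, orep + pos);
      if (c != cc) {
        // mismatch inside the chain: split cur into v1 (kept) + v2, add leaf v3
        int v2 = A.new_node(cc, cl - lp);
        A.kids[v2] = A.kids[cur];
        A.n_end[v2] = A.n_end[cur];
        A.enders[v2] = std::move(A.enders[cur]);
        A.rep[v2] = A.rep[cur];
        if (sorted) { A.r1[v2] = A.r1[cur]; A.r2[v2] = id - 1; }
        A.chain_len[cur] = lp - 1;
        A.kids[cur] = {-1, -1, -1, -1};
        A.kids[cur][cc] = v2;
        A.n_end[cur] = 0;
        A.enders[cur].clear();
        int v3 = A.new_node(c, L - pos - 1);
        A.rep[v3] = i;
        A.n_end[v3] = 1;
        A.enders[v3].assign(1, orig);
        if (sorted) { A.r1[v3] = id; A.r2[v3] = id; }
        A.kids[cur][c] = v3;
        return;
      }
      ++pos;
      ++lp;
    }
    if (pos == L) { // read ends exactly at the node boundary
      A.n_end[cur]++;
      A.enders[cur].push_back(orig);
      return;
    }
    A.comparisons++;
    int c = base_at(txt, o + pos);
    int nxt = A.kids[cur][c];
    if (nxt < 0) { // absent branch: fresh leaf
      int v3 = A.new_node(c, L - pos - 1);
      A.rep[v3] = i;
      A.n_end[v3] = 1;
      A.enders[v3].assign(1, orig);
      if (sorted) { A.r1[v3] = id; A.r2[v3] = id; }
      A.kids[cur][c] = v3;
      return;
    }
    cur = nxt;
    ++pos;
    if (sorted && id > A.r2[cur]) A.r2[cur] = id;
  }
}

static List arena_to_list(const Arena &A, double n_total) {
  int N = (int)A.label.size();
  IntegerVector lab(N), cl(N), r1(N), r2(N), ne(N);
  IntegerMatrix kids(4, N);
  List enders(N);
  for (int v = 0; v < N; ++v) {
    lab[v] = A.label[v] < 0 ? NA_INTEGER : A.label[v] + 1; // 1..4 = A,C,G,T
    cl[v] = A.chain_len[v];
    r1[v] = A.r1[v];
    r2[v] = A.r2[v];
    ne[v] = A.n_end[v];
    for (int c = 0; c < 4; ++c)
      kids(c, v) = A.kids[v][c] < 0 ? 0 : A.kids[v][c] + 1;
    enders[v] = A.enders[v].empty() ? R_NilValue
                                    : (SEXP)wrap(A.enders[v]);
  }
  return List::create(
      _["node_count"] = N, _["label_code"] = lab, _["chain_len"] = cl,
      _["r1"] = r1, _["r2"] = r2, _["n_end"] = ne, _["children"] = kids,
      _["enders"] = enders, _["comparisons"] = (double)A.comparisons,
      _["n"] = n_total);
}

// Build over reads given in insertion order.  `orig_index` holds the 1-based
// original indices of the reads in that order.  In sorted mode the order is
// assumed lexicographic and intervals are final; otherwise run cpp_relabel.
// [[Rcpp::export]]
List cpp_build(RawVector raw, IntegerVector offsets, IntegerVector lengths,
               IntegerVector orig_index, bool sorted) {
  Arena A;
  const unsigned char *txt = RAW(raw);
  int k = offsets.size();
  if (k == 0) stop("empty read set");
  double n_total = 0;
  for (int i = 0; i < k; ++i) {
    insert_read(A, txt, INTEGER(offsets), INTEGER(lengths), i, orig_index[i],
                sorted);
    n_total += lengths[i];
  }
  if (sorted) { A.r1[0] = 1; A.r2[0] = k; }
  return arena_to_list(A, n_total);
}

// Stage-2 DFS relabeling: assign consecutive ids in lexicographic (A<C<G<T,
// terminal-reads-first) order; returns updated intervals and the permutation
// original index -> id.
// [[Rcpp::export]]
List cpp_relabel(IntegerVector chain_len, IntegerMatrix children, List enders,
                 int k) {
  int N = chain_len.size();
  IntegerVector r1(N), r2(N);
  IntegerVector perm(k, NA_INTEGER);
  int counter = 1;
  // explicit stack of (node, next child slot)
  std::vector<std::pair<int, int>> st;
  st.push_back({0, 0});
  r1[0] = 1;
  {
    SEXP e = enders[0];
    if (e != R_NilValue) {
      IntegerVector ev(e);
      for (int j = 0; j < ev.size(); ++j) perm[ev[j] - 1] = counter++;
    }
  }
  while (!st.empty()) {
    int v = st.back().first;
    int c = st.back().second;
    if (c == 0 && v != 0) {
      r1[v] = counter;
      SEXP e = enders[v];
      if (e != R_NilValue) {
        IntegerVector ev(e);
        for (int j = 0; j < ev.size(); ++j) perm[ev[j] - 1] = counter++;
      }
    }
    if (c < 4) {
      st.back().second = c + 1;
      int ch = children(c, v);
      if (ch > 0) st.push_back({ch - 1, 0});
    } else {
      r2[v] = counter - 1;
      st.pop_back();
    }
  }
  return List::create(_["r1"] = r1, _["r2"] = r2, _["permutation"] = perm);
}

// ---------------------------------------------------------------- matching

// Walk one suffix down the trie.  Returns the 0-based node index where the
// suffix is exhausted, or -1 on mismatch / absent branch.  *at_boundary is
// set when exhaustion happens exactly at a node boundary (the full chain of
// the final node was consumed), the condition under which the suffix equals
// the complete string(s) ending at that node.
static int walk_suffix(const int *chain_len, const int *kids4, const int *r1,
                       const unsigned char *txt, const int *off_by_id,
                       long long qoff, int slen, long long *comps,
                       bool *at_boundary) {
  int cur = 0, pos = 0;
  for (;;) {
    const int cl = chain_len[cur];
    const long long orep =
        (cur == 0) ? 0 : (long long)off_by_id[r1[cur] - 1];
    for (int lp = 1; lp <= cl; ++lp) {
      if (pos == slen) { *at_boundary = false; return cur; }
      ++*comps;
      if (base_at(txt, qoff + pos) != base_at(txt, orep + pos)) return -1;
      ++pos;
    }
    if (pos == slen) { *at_boundary = true; return cur; }
    ++*comps;
    int c = base_at(txt, qoff + pos);
    int nxt = kids4[4 * cur + c];
    if (nxt == 0) return -1;
    cur = nxt - 1;
    ++pos;
  }
}

// Enumerate suffix-prefix matches.  Reads are addressed by lexicographic id;
// off_by_id / len_by_id give each id's slice of the encoded text.  mode:
// 0 = none (count only), 1 = longest_only, 2 = all_matches.
// [[Rcpp::export]]
List cpp_find_overlaps(IntegerVector chain_len, IntegerMatrix children,
                       IntegerVector r1, IntegerVector r2, RawVector raw,
                       IntegerVector off_by_id, IntegerVector len_by_id,
                       IntegerVector queries, int min_len, int mode,
                       bool include_self, LogicalVector removed_by_id) {
  const unsigned char *txt = RAW(raw);
  const int *cl = INTEGER(chain_len);
  const int *kids4 = INTEGER(children);
  const int *pr1 = INTEGER(r1), *pr2 = INTEGER(r2);
  const int *off = INTEGER(off_by_id);
  int k = off_by_id.size();
  bool any_removed = false;
  for (int t = 0; t < k; ++t)
    if (removed_by_id[t]) { any_removed = true; break; }

  std::vector<int> outq, outt, outl, outs;
  std::vector<int> stamp(k + 1, 0);
  double total = 0;
  NumericVector qcomps(queries.size());

  for (int qi = 0; qi < queries.size(); ++qi) {
    int q = queries[qi];
    int L = len_by_id[q - 1];
    long long qoff = off[q - 1];
    long long comps = 0;
    for (int j = 2; j <= L - min_len + 1; ++j) { // 1-based suffix start
      bool boundary = false;
      int v = walk_suffix(cl, kids4, pr1, txt, off, qoff + (j - 1), L - j + 1,
                          &comps, &boundary);
      if (v < 0) continue;
      int a = pr1[v], b = pr2[v];
      for (int t = a; t <= b; ++t) {
        if (t == q && !include_self) continue;
        if (any_removed && removed_by_id[t - 1]) continue;
        total += 1;
        if (mode == 2) {
          outq.push_back(q); outt.push_back(t);
          outl.push_back(L - j + 1); outs.push_back(j);
        } else if (mode == 1) {
          // suffixes are tested longest-first, so the first match per
          // ordered pair is the longest; stamp holds the last query to hit t
          if (stamp[t] == q) continue;
          stamp[t] = q;
          outq.push_back(q); outt.push_back(t);
          outl.push_back(L - j + 1); outs.push_back(j);
        }
      }
    }
    qcomps[qi] = (double)comps;
  }
  return List::create(_["query_id"] = wrap(outq), _["target_id"] = wrap(outt),
                      _["length"] = wrap(outl), _["start_pos"] = wrap(outs),
                      _["counts"] = total, _["comparisons"] = qcomps);
}

// Single-suffix probe used by match_suffix().  Returns interval or NULL.
// [[Rcpp::export]]
SEXP cpp_match_suffix(IntegerVector chain_len, IntegerMatrix children,
                      IntegerVector r1, IntegerVector r2, RawVector raw,
                      IntegerVector off_by_id, std::string suffix) {
  int slen = (int)suffix.size();
  if (slen == 0) return R_NilValue;
  // encode the probe into a scratch buffer appended logically: simplest is
  // to walk with direct character decoding of the probe.
  const unsigned char *txt = RAW(raw);
  const int *cl = INTEGER(chain_len);
  const int *kids4 = INTEGER(children);
  const int *pr1 = INTEGER(r1);
  const int *off = INTEGER(off_by_id);
  std::vector<int> probe(slen);
  for (int i = 0; i < slen; ++i) {
    probe[i] = code_of(suffix[i]);
    if (probe[i] < 0) stop("suffix contains a non-ACGT character");
  }
  int cur = 0, pos = 0;
  for (;;) {
    const int c_len = cl[cur];
    const long long orep = (cur == 0) ? 0 : (long long)off[pr1[cur] - 1];
    for (int lp = 1; lp <= c_len; ++lp) {
      if (pos == slen)
        return IntegerVector::create(r1[cur], r2[cur]);
      if (probe[pos] != base_at(txt, orep + pos)) return R_NilValue;
      ++pos;
    }
    if (pos == slen) return IntegerVector::create(r1[cur], r2[cur]);
    int nxt = kids4[4 * cur + probe[pos]];
    if (nxt == 0) return R_NilValue;
    cur = nxt - 1;
    ++pos;
  }
}

// Suffix-containment scan: walk every proper suffix of every read; a node is
// hit when some suffix is exhausted exactly at its boundary and reads end
// there (those reads equal that suffix).  Returns a logical vector over
// nodes.
// [[Rcpp::export]]
LogicalVector cpp_suffix_containment(IntegerVector chain_len,
                                     IntegerMatrix children, IntegerVector r1,
                                     IntegerVector n_end, RawVector raw,
                                     IntegerVector off_by_id,
                                     IntegerVector len_by_id) {
  const unsigned char *txt = RAW(raw);
  const int *cl = INTEGER(chain_len);
  const int *kids4 = INTEGER(children);
  const int *pr1 = INTEGER(r1);
  const int *off = INTEGER(off_by_id);
  int k = off_by_id.size();
  LogicalVector hit(chain_len.size(), false);
  long long comps = 0;
  for (int q = 1; q <= k; ++q) {
    int L = len_by_id[q - 1];
    long long qoff = off[q - 1];
    for (int j = 2; j <= L; ++j) {
      bool boundary = false;
      int v = walk_suffix(cl, kids4, pr1, txt, off, qoff + (j - 1), L - j + 1,
                          &comps, &boundary);
      if (v >= 0 && boundary && n_end[v] > 0) hit[v] = true;
    }
  }
  return hit;
}
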