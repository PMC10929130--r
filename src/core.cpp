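#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Suffix array by prefix doubling (O(n log^2 n)); fine at the scales this
// package targets. `codes` is the text with its terminator appended, as
// positive integer symbol codes. Returns 1-based suffix start positions.
// [[Rcpp::export]]
IntegerVector cpp_suffix_array(IntegerVector codes) {
  const int n = codes.size();
  std::vector<int> sa(n), r(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; r[i] = codes[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (r[a] != r[b]) return r[a] < r[b];
      int ra = a + k < n ? r[a + k] : -1;
      int rb = b + k < n ? r[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    r = tmp;
    if (r[sa[n - 1]] == n - 1 || k >= n) break;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sa[i] + 1;
  return out;
}

// ---------------------------------------------------------------------------
// Bidirectional index primitives over occurrence-count matrices.
// occ matrices are (n+1) x sigma cumulative counts: occ(r, c-1) = number of
// occurrences of code c in bwt[1..r]; row 0 is all zeros. C[c-1] = number of
// symbols in the text (terminator included) with code < c.

struct Idx {
  const int *of, *orv;   // column-major (n+1) x sigma
  const int *C;
  int n;                 // text length incl. terminator
  int sigma;
  inline int cntF(int row, int c) const { return of[(c - 1) * (n + 1) + row]; }
  inline int cntR(int row, int c) const { return orv[(c - 1) * (n + 1) + row]; }
};

struct Iv { int i, j, ri, rj; };
static inline bool empty_iv(const Iv &v) { return v.j < v.i; }

static Idx make_idx(List L) {
  Idx x;
  IntegerMatrix of = L["of"], orv = L["orv"];
  IntegerVector C = L["C"];
  x.of = INTEGER(of); x.orv = INTEGER(orv); x.C = INTEGER(C);
  x.sigma = of.ncol();
  x.n = of.nrow() - 1;
  return x;
}

static Iv ext_left(const Idx &x, int c, const Iv &v) {
  int before = x.cntF(v.i - 1, c);
  int cnt = x.cntF(v.j, c) - before;
  if (cnt == 0) return Iv{1, 0, 1, 0};
  int smaller = 0;
  for (int b = 1; b < c; ++b) smaller += x.cntF(v.j, b) - x.cntF(v.i - 1, b);
  Iv o;
  o.i = x.C[c - 1] + before + 1;
  o.j = o.i + cnt - 1;
  o.ri = v.ri + smaller;
  o.rj = o.ri + cnt - 1;
  return o;
}

static Iv ext_right(const Idx &x, int c, const Iv &v) {
  int before = x.cntR(v.ri - 1, c);
  int cnt = x.cntR(v.rj, c) - before;
  if (cnt == 0) return Iv{1, 0, 1, 0};
  int smaller = 0;
  for (int b = 1; b < c; ++b) smaller += x.cntR(v.rj, b) - x.cntR(v.ri - 1, b);
  Iv o;
  o.ri = x.C[c - 1] + before + 1;
  o.rj = o.ri + cnt - 1;
  o.i = v.i + smaller;
  o.j = o.i + cnt - 1;
  return o;
}

static void enum_left(const Idx &x, const Iv &v, std::vector<int> &out) {
  out.clear();
  for (int c = 1; c <= x.sigma; ++c)
    if (x.cntF(v.j, c) - x.cntF(v.i - 1, c) > 0) out.push_back(c);
}

static void enum_right(const Idx &x, const Iv &v, std::vector<int> &out) {
  out.clear();
  for (int c = 1; c <= x.sigma; ++c)
    if (x.cntR(v.rj, c) - x.cntR(v.ri - 1, c) > 0) out.push_back(c);
}

// Union size of two sorted code sets where the end-marker code counts as a
// distinct symbol per side (occurrences ending at the boundary of Q and of T
// see different sentinels in the virtual concatenation T#Q).
static int union_size(const std::vector<int> &a, const std::vector<int> &b,
                      int dollar) {
  size_t i = 0, j = 0; int n = 0; bool da = false, db = false;
  while (i < a.size() || j < b.size()) {
    int va = i < a.size() ? a[i] : INT32_MAX;
    int vb = j < b.size() ? b[j] : INT32_MAX;
    int v = std::min(va, vb);
    if (va == v) { ++i; if (v == dollar) da = true; }
    if (vb == v) { ++j; if (v == dollar) db = true; }
    ++n;
  }
  if (da && db) ++n;
  return n;
}

// ---------------------------------------------------------------------------
// Sparse-table RMQ (argmin) with NA treated as +infinity.

struct Rmq {
  std::vector<int> vals;          // copy with NA -> INT_MAX
  std::vector<std::vector<int>> tab;
  void build(const IntegerVector &v) {
    int n = v.size();
    vals.resize(n);
    for (int i = 0; i < n; ++i)
      vals[i] = (v[i] == NA_INTEGER) ? INT32_MAX : v[i];
    int lv = 1;
    while ((1 << lv) <= n) ++lv;
    tab.assign(lv, std::vector<int>(n));
    for (int i = 0; i < n; ++i) tab[0][i] = i;
    for (int l = 1; l < lv; ++l) {
      int half = 1 << (l - 1);
      for (int i = 0; i + (1 << l) <= n; ++i) {
        int a = tab[l - 1][i], b = tab[l - 1][i + half];
        tab[l][i] = vals[a] <= vals[b] ? a : b;
      }
    }
  }
  // 0-based inclusive
  int query(int lo, int hi) const {
    int l = 0;
    while ((1 << (l + 1)) <= hi - lo + 1) ++l;
    int a = tab[l][lo], b = tab[l][hi - (1 << l) + 1];
    return vals[a] <= vals[b] ? a : b;
  }
  // report all k in [lo..hi] (0-based) with vals[k] <= delta; counts queries
  int report(int lo, int hi, int delta, std::vector<int> &out) {
    int calls = 0;
    std::vector<std::pair<int, int>> st;
    if (lo <= hi) st.push_back({lo, hi});
    while (!st.empty()) {
      auto pr = st.back(); st.pop_back();
      if (pr.first > pr.second) continue;
      int k = query(pr.first, pr.second); ++calls;
      if (vals[k] > delta) continue;
      out.push_back(k);
      if (pr.first <= k - 1) st.push_back({pr.first, k - 1});
      if (k + 1 <= pr.second) st.push_back({k + 1, pr.second});
    }
    return calls;
  }
};

// Threshold reporting on an integer array (1-based interface for R).
// Returns the matching indices and the number of RMQ probes used.
// [[Rcpp::export]]
List cpp_rmq_report(IntegerVector values, int lo, int hi, double delta) {
  Rmq r; r.build(values);
  std::vector<int> out;
  int calls = 0;
  int d = delta >= (double)INT32_MAX ? INT32_MAX - 1 : (int)delta;
  if (lo <= hi) calls = r.report(lo - 1, hi - 1, d, out);
  IntegerVector idx(out.size());
  for (size_t i = 0; i < out.size(); ++i) idx[i] = out[i] + 1;
  return List::create(_["indices"] = idx, _["calls"] = calls);
}

// ---------------------------------------------------------------------------
// MEM-candidate exploration and cross product.
//
// Walks all strings that occur in both Q and T and are right-maximal in the
// virtual concatenation T#Q, by left extension with plain alphabet symbols
// (codes >= min_ext_code). Each candidate of length >= kappa that is also
// left-maximal in T#Q goes through the cross product: A-side classes (a,b)
// around the candidate in Q, B-side classes (c,d) in T with codes listed in
// `exclude_t` skipped, pairs kept when a != c and b != d (the end marker
// counts as distinct per side). With a D array present, T-side suffix-array
// positions are filtered to D[k] <= |Q'| + 1 via recursive RMQ reporting.
// [[Rcpp::export]]
List cpp_explore(List idxQ, List idxT, int kappa, int min_ext_code,
                 IntegerVector exclude_t, int dollar_code,
                 Nullable<IntegerVector> d_array, bool collect_candidates) {
  Idx Q = make_idx(idxQ), T = make_idx(idxT);
  bool use_d = d_array.isNotNull();
  Rmq rmq;
  if (use_d) rmq.build(d_array.get());

  bool excl[64] = {false};
  for (int i = 0; i < exclude_t.size(); ++i) excl[exclude_t[i]] = true;

  struct Frame { Iv q, t; int len; };
  std::vector<Frame> stack;
  stack.push_back({Iv{1, Q.n, 1, Q.n}, Iv{1, T.n, 1, T.n}, 0});

  long nodes = 0, ncand = 0;
  int clsctr = 0;  // global (a,b,c,d)-class counter across candidates
  std::vector<int> out_kq, out_kt, out_len, out_cls;
  std::vector<int> cand_k, cand_len;
  std::vector<int> elq, elt, erq, ert;

  struct Acls { int a, b, i, j; };
  struct Bcls { int c, d; std::vector<int> ks; };
  std::vector<Acls> A;
  std::vector<Bcls> B;

  while (!stack.empty()) {
    Frame f = stack.back(); stack.pop_back();
    ++nodes;
    if ((nodes & 0x3FF) == 0) Rcpp::checkUserInterrupt();

    enum_left(Q, f.q, elq);
    enum_left(T, f.t, elt);

    if (f.len >= kappa &&
        union_size(elq, elt, dollar_code) >= 2) {
      // MEM candidate: cross product
      ++ncand;
      if (collect_candidates) { cand_k.push_back(f.q.i); cand_len.push_back(f.len); }
      A.clear(); B.clear();
      for (int a : elq) {
        Iv qa = ext_left(Q, a, f.q);
        enum_right(Q, qa, erq);
        for (int b : erq) {
          Iv qab = ext_right(Q, b, qa);
          A.push_back({a, b, qab.i, qab.j});
        }
      }
      for (int c : elt) {
        if (excl[c]) continue;
        Iv tc = ext_left(T, c, f.t);
        enum_right(T, tc, ert);
        for (int d : ert) {
          if (excl[d]) continue;
          Iv tcd = ext_right(T, d, tc);
          Bcls bc; bc.c = c; bc.d = d;
          if (use_d) {
            // D[k] counts from the extension character c (one before the
            // match), so the match itself reaches the last node iff
            // D[k] <= |Q'|.
            std::vector<int> ks0;
            rmq.report(tcd.i - 1, tcd.j - 1, f.len, ks0);
            for (int k : ks0) bc.ks.push_back(k + 1);
          } else {
            for (int k = tcd.i; k <= tcd.j; ++k) bc.ks.push_back(k);
          }
          if (!bc.ks.empty()) B.push_back(std::move(bc));
        }
      }
      for (const Acls &ac : A)
        for (const Bcls &bc : B) {
          bool lok = (ac.a != bc.c) || (ac.a == dollar_code);
          bool rok = (ac.b != bc.d) || (ac.b == dollar_code);
          if (!lok || !rok) { ++clsctr; continue; }
          for (int kq = ac.i; kq <= ac.j; ++kq)
            for (int kt : bc.ks) {
              out_kq.push_back(kq);
              out_kt.push_back(kt);
              out_len.push_back(f.len);
              out_cls.push_back(clsctr);
            }
          ++clsctr;
        }
    }

    // left extensions with plain alphabet symbols occurring in Q
    for (int c : elq) {
      if (c < min_ext_code) continue;
      Iv nq = ext_left(Q, c, f.q);
      Iv nt = ext_left(T, c, f.t);
      if (empty_iv(nt)) continue;
      enum_right(Q, nq, erq);
      enum_right(T, nt, ert);
      if (union_size(erq, ert, dollar_code) >= 2)
        stack.push_back({nq, nt, f.len + 1});
    }
  }

  List res = List::create(
    _["kq"] = wrap(out_kq), _["kt"] = wrap(out_kt),
    _["len"] = wrap(out_len), _["cls"] = wrap(out_cls),
    _["nodes"] = (double)nodes, _["candidates"] = (double)ncand);
  if (collect_candidates) {
    res["cand_k"] = wrap(cand_k);
    res["cand_len"] = wrap(cand_len);
  }
  return res;
}

// ---------------------------------------------------------------------------
// Per-edge scan over the query index for the relaxed EFG MEM classes.
//
// For each pattern (the concatenated labels of an edge), searches it in the
// index of Q; backward (forward = false) for edge-suffix / full-node reports,
// forward (forward = true) for edge-prefix / full-node reports. `boundary`
// holds, per pattern, the number of symbols after which the node boundary is
// crossed (|l(v)| when searching backward, |l(u)| forward). Reporting starts
// at the boundary: at each step the occurrences that fail to extend with the
// next label symbol (or hit the start/end of Q) are emitted; when the whole
// pattern is matched every remaining occurrence is emitted.
// [[Rcpp::export]]
List cpp_edge_scan(List idxQ, IntegerVector saQ, IntegerVector qcodes,
                   List patterns, IntegerVector boundary, bool forward) {
  Idx Q = make_idx(idxQ);
  int nq = Q.n;  // incl. terminator
  std::vector<int> out_edge, out_q, out_len, out_full;
  for (int e = 0; e < patterns.size(); ++e) {
    IntegerVector pat = patterns[e];
    int plen = pat.size(), bnd = boundary[e];
    Iv iv{1, nq, 1, nq};
    for (int s = 1; s <= plen; ++s) {
      int c = forward ? pat[s - 1] : pat[plen - s];
      iv = forward ? ext_right(Q, c, iv) : ext_left(Q, c, iv);
      if (empty_iv(iv)) break;
      if (s < bnd) continue;
      int nxt = 0;
      if (s < plen) nxt = forward ? pat[s] : pat[plen - s - 1];
      for (int k = iv.i; k <= iv.j; ++k) {
        int start = saQ[k - 1];              // 1-based occurrence start in Q
        if (start + s - 1 > nq - 1) continue; // cannot touch the terminator
        bool rep;
        if (s == plen) rep = true;
        else if (forward) {
          int after = start + s;             // next query position
          rep = (after > nq - 1) || (qcodes[after - 1] != nxt);
        } else {
          rep = (start == 1) || (qcodes[start - 2] != nxt);
        }
        if (rep) {
          out_edge.push_back(e + 1);
          out_q.push_back(start);
          out_len.push_back(s);
          out_full.push_back(s == bnd ? 1 : 0);
        }
      }
    }
  }
  return List::create(_["edge"] = wrap(out_edge), _["qstart"] = wrap(out_q),
                      _["len"] = wrap(out_len), _["at_boundary"] = wrap(out_full));
}
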