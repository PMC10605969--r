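// Core routines that are too hot for interpreted R: suffix-array
// construction, execution of search schemes over the bidirectional FM-index,
// and a brute-force banded edit-distance scanner used as an independent
// reference in tests and validation.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Suffix array by prefix doubling, O(n log^2 n).  Input: integer codes
// (alphabet order is the code order); output: 0-based suffix array.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector sa_build_cpp(IntegerVector codes) {
  const int n = codes.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> sa(n), rnk(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rnk[i] = codes[i]; }
  for (int len = 1;; len <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = a + len < n ? rnk[a + len] : -1;
      int rb = b + len < n ? rnk[b + len] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1) break;
  }
  return wrap(sa);
}

// ---------------------------------------------------------------------------
// Bidirectional FM-index primitives (shared by the scheme executor).
// occ / occ_r are (n+1) x 6 cumulative character-count matrices over
// BWT / BWT^r; C is the length-7 cumulative alphabet count vector.
// Character codes: $=0, %=1, A=2, C=3, G=4, T=5.
// ---------------------------------------------------------------------------

struct FM {
  const int *C;
  const int *occ;    // column-major, column c starts at c*(n+1)
  const int *occ_r;
  int n;
};

struct BdRange {
  int b, e, br, er;
  bool empty() const { return e <= b; }
};

static inline BdRange extend_back(const FM &fm, const BdRange &r, int c) {
  const int stride = fm.n + 1;
  const int *col = fm.occ + (size_t)c * stride;
  int b2 = fm.C[c] + col[r.b];
  int e2 = fm.C[c] + col[r.e];
  int br2 = r.br;
  for (int cc = 0; cc < c; ++cc) {
    const int *cl = fm.occ + (size_t)cc * stride;
    br2 += cl[r.e] - cl[r.b];
  }
  BdRange out;
  out.b = b2; out.e = e2; out.br = br2; out.er = br2 + (e2 - b2);
  return out;
}

static inline BdRange extend_fwd(const FM &fm, const BdRange &r, int c) {
  const int stride = fm.n + 1;
  const int *col = fm.occ_r + (size_t)c * stride;
  int br2 = fm.C[c] + col[r.br];
  int er2 = fm.C[c] + col[r.er];
  int b2 = r.b;
  for (int cc = 0; cc < c; ++cc) {
    const int *cl = fm.occ_r + (size_t)cc * stride;
    b2 += cl[r.er] - cl[r.br];
  }
  BdRange out;
  out.b = b2; out.e = b2 + (er2 - br2);
  out.br = br2; out.er = er2;
  return out;
}

// ---------------------------------------------------------------------------
// Search-scheme execution under edit distance.
//
// Each search processes the pattern parts in pi order; the alignment is
// re-anchored at every part boundary: within a part a full-row dynamic
// programming table (Ukkonen cutoff at the part's upper bound) aligns the
// spelled occurrence segment against the part, and every attainable
// final-column value within [L, U] branches into the next part.  Occurrence
// candidates are spelled over A/C/G/T only: matches never contain a
// separation character.
// ---------------------------------------------------------------------------

struct SchemeCtx {
  FM fm;
  const std::vector<int> *pat;
  std::vector<int> part_starts;          // p+1 boundaries
  // per-search, filled before execution:
  std::vector<std::vector<int> > segs;   // segment codes per pi position
  std::vector<int> dirs;                 // +1 forward, -1 backward
  std::vector<int> Lb, Ub;
  int p;
  // results
  std::vector<int> ob, oe, obr, oer, olen, oed;
};

static void run_part(SchemeCtx &ctx, int idx, const BdRange &r0, int len0,
                     int base);

static void complete_part(SchemeCtx &ctx, int idx, const BdRange &r, int len,
                          int v) {
  if (v < ctx.Lb[idx] || v > ctx.Ub[idx]) return;
  if (idx == ctx.p - 1) {
    if (len < 1) return;
    ctx.ob.push_back(r.b);   ctx.oe.push_back(r.e);
    ctx.obr.push_back(r.br); ctx.oer.push_back(r.er);
    ctx.olen.push_back(len); ctx.oed.push_back(v);
  } else {
    run_part(ctx, idx + 1, r, len, v);
  }
}

// Depth-first extension within part `idx`.
static void extend_in_part(SchemeCtx &ctx, int idx, const std::vector<int> &X,
                           int dir, const BdRange &r, int len, int base,
                           const std::vector<int> &row) {
  const int m = (int)X.size();
  // a branch may close the part at the current number of spelled characters
  complete_part(ctx, idx, r, len, row[m]);
  int rmin = row[0];
  for (int j = 1; j <= m; ++j) rmin = std::min(rmin, row[j]);
  if (rmin > ctx.Ub[idx]) return;
  std::vector<int> nxt(m + 1);
  for (int c = 2; c <= 5; ++c) {
    BdRange nr = (dir > 0) ? extend_fwd(ctx.fm, r, c)
                           : extend_back(ctx.fm, r, c);
    if (nr.empty()) continue;
    nxt[0] = row[0] + 1;
    for (int j = 1; j <= m; ++j) {
      int best = row[j] + 1;                       // char of O unmatched
      int ins = nxt[j - 1] + 1;                    // char of P unmatched
      if (ins < best) best = ins;
      int diag = row[j - 1] + (c == X[j - 1] ? 0 : 1);
      if (diag < best) best = diag;
      nxt[j] = best;
    }
    extend_in_part(ctx, idx, X, dir, nr, len + 1, base, nxt);
  }
}

static void run_part(SchemeCtx &ctx, int idx, const BdRange &r0, int len0,
                     int base) {
  const std::vector<int> &X = ctx.segs[idx];
  const int m = (int)X.size();
  std::vector<int> row(m + 1);
  for (int j = 0; j <= m; ++j) row[j] = base + j;
  extend_in_part(ctx, idx, X, ctx.dirs[idx], r0, len0, base, row);
}

// searches: list of list(pi=, L=, U=) with 0-based pi.
// part_starts: 0-based boundaries of length p+1.
// Returns a matrix with columns b, e, br, er, len, ed (0-based bounds),
// deduplicated on (b, len) keeping the minimal edit distance.
// [[Rcpp::export]]
IntegerMatrix scheme_match_cpp(IntegerVector C, IntegerMatrix occ,
                               IntegerMatrix occ_r, IntegerVector pattern,
                               int K, List searches,
                               IntegerVector part_starts) {
  SchemeCtx ctx;
  ctx.fm.C = INTEGER(C);
  ctx.fm.occ = INTEGER(occ);
  ctx.fm.occ_r = INTEGER(occ_r);
  ctx.fm.n = occ.nrow() - 1;
  std::vector<int> pat(pattern.begin(), pattern.end());
  ctx.pat = &pat;
  ctx.part_starts.assign(part_starts.begin(), part_starts.end());
  const int p = (int)part_starts.size() - 1;
  ctx.p = p;

  for (int s = 0; s < searches.size(); ++s) {
    List sr = searches[s];
    IntegerVector pi = sr["pi"], L = sr["L"], U = sr["U"];
    ctx.segs.assign(p, std::vector<int>());
    ctx.dirs.assign(p, +1);
    ctx.Lb.assign(L.begin(), L.end());
    ctx.Ub.assign(U.begin(), U.end());
    int lo = pi[0], hi = pi[0];
    for (int idx = 0; idx < p; ++idx) {
      int part = pi[idx], dir;
      if (idx == 0) {
        dir = +1;
      } else if (part == hi + 1) {
        dir = +1; hi = part;
      } else if (part == lo - 1) {
        dir = -1; lo = part;
      } else {
        stop("search %d violates the connectivity property", s);
      }
      std::vector<int> seg;
      for (int t = ctx.part_starts[part]; t < ctx.part_starts[part + 1]; ++t)
        seg.push_back(pat[t]);
      if (dir < 0) std::reverse(seg.begin(), seg.end());
      ctx.segs[idx] = seg;
      ctx.dirs[idx] = dir;
    }
    BdRange full; full.b = 0; full.e = ctx.fm.n; full.br = 0; full.er = ctx.fm.n;
    run_part(ctx, 0, full, 0, 0);
  }

  // deduplicate on (b, len), keep minimal edit distance
  const int nrec = (int)ctx.ob.size();
  std::vector<int> ord(nrec);
  for (int i = 0; i < nrec; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (ctx.ob[a] != ctx.ob[b]) return ctx.ob[a] < ctx.ob[b];
    if (ctx.olen[a] != ctx.olen[b]) return ctx.olen[a] < ctx.olen[b];
    return ctx.oed[a] < ctx.oed[b];
  });
  std::vector<int> keep;
  for (int i = 0; i < nrec; ++i) {
    int cur = ord[i];
    if (!keep.empty()) {
      int prv = keep.back();
      if (ctx.ob[prv] == ctx.ob[cur] && ctx.olen[prv] == ctx.olen[cur])
        continue;
    }
    keep.push_back(cur);
  }
  IntegerMatrix out((int)keep.size(), 6);
  colnames(out) = CharacterVector::create("b", "e", "br", "er", "len", "ed");
  for (int i = 0; i < (int)keep.size(); ++i) {
    int j = keep[i];
    out(i, 0) = ctx.ob[j];  out(i, 1) = ctx.oe[j];
    out(i, 2) = ctx.obr[j]; out(i, 3) = ctx.oer[j];
    out(i, 4) = ctx.olen[j]; out(i, 5) = ctx.oed[j];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Brute-force reference scanner: every substring T[s, s+len[ over A/C/G/T
// with edit distance <= K to the pattern, by banded dynamic programming from
// each start position.  Independent of the FM-index machinery above.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix brute_occurrences_cpp(IntegerVector text, IntegerVector pattern,
                                    int K) {
  const int n = text.size(), m = pattern.size();
  const int INF = 1 << 28;
  std::vector<int> starts, lens, eds;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int s = 0; s < n; ++s) {
    if (text[s] < 2) continue;              // cannot start at a separator
    for (int j = 0; j <= m; ++j) prev[j] = (j <= K) ? j : INF;
    const int imax = std::min(n - s, m + K);
    for (int i = 1; i <= imax; ++i) {
      const int c = text[s + i - 1];
      if (c < 2) break;                     // never spans a separator
      const int lo = std::max(0, i - K), hi = std::min(m, i + K);
      int rmin = INF;
      for (int j = 0; j <= m; ++j) cur[j] = INF;
      if (lo == 0) cur[0] = i;
      for (int j = std::max(1, lo); j <= hi; ++j) {
        int best = INF;
        if (prev[j] < INF) best = prev[j] + 1;
        if (cur[j - 1] < INF) best = std::min(best, cur[j - 1] + 1);
        if (prev[j - 1] < INF)
          best = std::min(best,
                          prev[j - 1] + (c == pattern[j - 1] ? 0 : 1));
        cur[j] = best;
      }
      for (int j = lo; j <= hi; ++j) rmin = std::min(rmin, cur[j]);
      if (hi == m && cur[m] <= K) {
        starts.push_back(s); lens.push_back(i); eds.push_back(cur[m]);
      }
      if (rmin > K) break;
      std::swap(prev, cur);
    }
  }
  IntegerMatrix out((int)starts.size(), 3);
  colnames(out) = CharacterVector::create("start", "len", "ed");
  for (int i = 0; i < (int)starts.size(); ++i) {
    out(i, 0) = starts[i]; out(i, 1) = lens[i]; out(i, 2) = eds[i];
  }
  return out;
}
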