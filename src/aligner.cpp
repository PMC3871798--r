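// Alignment engines for fixed RNA secondary structures.
//
// Scores are integers: the R side scales the weighted substitution tables and
// gap parameters by 100 and rounds, so every optimum is an exact integer and
// the baseline and sparse engines agree bit-for-bit regardless of the order in
// which partial scores are summed.
//
// Conventions: sequence positions are 1-based inclusive; pair index 0 is the
// pseudo-root (0, l+1); a region with start > end is empty. A gap run of
// length k costs g + k*e (g = open, e = extend, both negative, g < e).

#include <Rcpp.h>
#include <climits>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

static const long long NEG = LLONG_MIN / 4;

struct Scheme {
  std::vector<long long> R25, D5;
  long long g, e, rmax, dmax;
  long long rowmax[5];  // per-nucleotide best substitution score
  long long nt(int a, int b) const { return D5[a * 5 + b]; }
  long long bp(int d1, int d2) const { return R25[d1 * 25 + d2]; }
};

struct Str {
  std::vector<int> seq;    // codes 0..4 (A,C,G,U,N)
  int l = 0, n = 0;
  std::vector<int> L, R;   // index 1..n sorted by R ascending; [0] = root (0, l+1)
  std::vector<int> endat;  // position -> pair index ending there (0 = none)
  std::vector<int> dn;     // pair index -> dinucleotide code
};

static Str make_str(List s) {
  Str t;
  IntegerVector sq = s["seq"], L = s["left"], R = s["right"];
  t.seq.assign(sq.begin(), sq.end());
  t.l = (int)t.seq.size();
  t.n = (int)L.size();
  t.L.resize(t.n + 1);
  t.R.resize(t.n + 1);
  t.dn.resize(t.n + 1, 0);
  t.L[0] = 0;
  t.R[0] = t.l + 1;
  t.endat.assign(t.l + 2, 0);
  for (int i = 0; i < t.n; i++) {
    t.L[i + 1] = L[i];
    t.R[i + 1] = R[i];
    t.endat[R[i]] = i + 1;
    t.dn[i + 1] = 5 * t.seq[L[i] - 1] + t.seq[R[i] - 1];
  }
  return t;
}

static Scheme make_scheme(List sc) {
  Scheme S;
  IntegerMatrix R = sc["R"], D = sc["D"];
  S.R25.resize(625);
  S.D5.resize(25);
  for (int i = 0; i < 25; i++)
    for (int j = 0; j < 25; j++) S.R25[i * 25 + j] = R(i, j);
  for (int i = 0; i < 5; i++)
    for (int j = 0; j < 5; j++) S.D5[i * 5 + j] = D(i, j);
  S.g = as<int>(sc["g"]);
  S.e = as<int>(sc["e"]);
  S.rmax = as<int>(sc["r_max"]);
  S.dmax = as<int>(sc["d_max"]);
  for (int a = 0; a < 5; a++) {
    S.rowmax[a] = S.D5[a * 5];
    for (int b = 1; b < 5; b++) S.rowmax[a] = std::max(S.rowmax[a], S.D5[a * 5 + b]);
  }
  return S;
}

static inline long long max3(long long a, long long b, long long c) {
  return std::max(a, std::max(b, c));
}

// Memoised affine-gap global alignment (score only) of subregions.
struct SimCache {
  const Str *A, *B;
  const Scheme *S;
  std::unordered_map<uint64_t, long long> memo;
  long long computed = 0;

  long long score(int as, int ae, int bs, int be) {
    int n = std::max(0, ae - as + 1), m = std::max(0, be - bs + 1);
    if (n == 0 && m == 0) return 0;
    if (n == 0) return S->g + (long long)m * S->e;
    if (m == 0) return S->g + (long long)n * S->e;
    uint64_t key = ((uint64_t)as << 48) | ((uint64_t)ae << 32) |
                   ((uint64_t)bs << 16) | (uint64_t)be;
    auto it = memo.find(key);
    if (it != memo.end()) return it->second;
    computed++;
    std::vector<long long> Mm(m + 1), Ix(m + 1), Iy(m + 1),
        pM(m + 1), pX(m + 1), pY(m + 1);
    pM[0] = 0;
    pX[0] = pY[0] = NEG;
    for (int j = 1; j <= m; j++) {
      pY[j] = S->g + (long long)j * S->e;
      pM[j] = pX[j] = NEG;
    }
    for (int i = 1; i <= n; i++) {
      Mm[0] = Iy[0] = NEG;
      Ix[0] = S->g + (long long)i * S->e;
      int a = A->seq[as - 1 + i - 1];
      for (int j = 1; j <= m; j++) {
        int b = B->seq[bs - 1 + j - 1];
        Mm[j] = max3(pM[j - 1], pX[j - 1], pY[j - 1]) + S->nt(a, b);
        Ix[j] = max3(pM[j] + S->g + S->e, pX[j] + S->e, pY[j] + S->g + S->e);
        Iy[j] = max3(Mm[j - 1] + S->g + S->e, Ix[j - 1] + S->g + S->e,
                     Iy[j - 1] + S->e);
      }
      std::swap(Mm, pM);
      std::swap(Ix, pX);
      std::swap(Iy, pY);
    }
    long long res = max3(pM[m], pX[m], pY[m]);
    memo[key] = res;
    return res;
  }
};

// Interior (or span) alignment of A[as..ae] x B[bs..be] with arc transitions.
// An arc is available for every couple (pa, pb) whose spans lie within the
// region and whose M value is known; taking it adds M[pa, pb] and consumes
// both spans. Affine gap state does not persist across an arc, so each loop
// segment delimited by matched pairs is aligned independently. Tracks an
// arc-used flag: mh_out is the arc-free optimum (the hairpin interpretation,
// every inner pair broken), ml_out the optimum using at least one arc.
typedef std::unordered_set<uint64_t> ArcSet;
static inline uint64_t arc_key(int pa, int pb) {
  return ((uint64_t)pa << 20) | (uint64_t)pb;
}

static void cell_dp(const Str& A, int as, int ae, const Str& B, int bs, int be,
                    const Scheme& S,
                    const std::vector<std::vector<long long>>& Mtab,
                    long long& mh_out, long long& ml_out,
                    const ArcSet* arcs = nullptr) {
  int n = std::max(0, ae - as + 1), m = std::max(0, be - bs + 1);
  ml_out = NEG;
  if (n == 0 || m == 0) {
    mh_out = (n == 0 && m == 0) ? 0 : (S.g + (long long)(n + m) * S.e);
    return;
  }
  std::vector<long long> best((size_t)(n + 1) * (m + 1), NEG);
  std::vector<long long> M0(m + 1), X0(m + 1), Y0(m + 1),
      M1(m + 1), X1(m + 1), Y1(m + 1),
      pM0(m + 1), pX0(m + 1), pY0(m + 1), pM1(m + 1), pX1(m + 1), pY1(m + 1);
  pM0[0] = 0;
  pX0[0] = pY0[0] = pM1[0] = pX1[0] = pY1[0] = NEG;
  best[0] = 0;
  for (int j = 1; j <= m; j++) {
    pY0[j] = S.g + (long long)j * S.e;
    pM0[j] = pX0[j] = pM1[j] = pX1[j] = pY1[j] = NEG;
    best[j] = pY0[j];
  }
  for (int i = 1; i <= n; i++) {
    M0[0] = Y0[0] = M1[0] = X1[0] = Y1[0] = NEG;
    X0[0] = S.g + (long long)i * S.e;
    best[(size_t)i * (m + 1)] = X0[0];
    int ai = as - 1 + i;
    int pa = A.endat[ai];
    bool paok = pa > 0 && A.L[pa] >= as;
    int a = A.seq[ai - 1];
    for (int j = 1; j <= m; j++) {
      int bj = bs - 1 + j;
      int b = B.seq[bj - 1];
      long long sub = S.nt(a, b);
      M0[j] = max3(pM0[j - 1], pX0[j - 1], pY0[j - 1]) + sub;
      X0[j] = max3(pM0[j] + S.g + S.e, pX0[j] + S.e, pY0[j] + S.g + S.e);
      Y0[j] = max3(M0[j - 1] + S.g + S.e, X0[j - 1] + S.g + S.e,
                   Y0[j - 1] + S.e);
      M1[j] = max3(pM1[j - 1], pX1[j - 1], pY1[j - 1]) + sub;
      X1[j] = max3(pM1[j] + S.g + S.e, pX1[j] + S.e, pY1[j] + S.g + S.e);
      Y1[j] = max3(M1[j - 1] + S.g + S.e, X1[j - 1] + S.g + S.e,
                   Y1[j - 1] + S.e);
      if (paok) {
        int pb = B.endat[bj];
        if (pb > 0 && B.L[pb] >= bs && (!arcs || arcs->count(arc_key(pa, pb)))) {
          long long mv = Mtab[pa][pb];
          if (mv > NEG) {
            long long src =
                best[(size_t)(A.L[pa] - as) * (m + 1) + (B.L[pb] - bs)];
            if (src > NEG && src + mv > M1[j]) M1[j] = src + mv;
          }
        }
      }
      best[(size_t)i * (m + 1) + j] =
          std::max(max3(M0[j], X0[j], Y0[j]), max3(M1[j], X1[j], Y1[j]));
    }
    std::swap(M0, pM0); std::swap(X0, pX0); std::swap(Y0, pY0);
    std::swap(M1, pM1); std::swap(X1, pX1); std::swap(Y1, pY1);
  }
  mh_out = max3(pM0[m], pX0[m], pY0[m]);
  ml_out = max3(pM1[m], pX1[m], pY1[m]);
}

// Single-value variant: the unrestricted optimum of the region (hairpin and
// multi-loop interpretations combined), with arcs limited to a candidate set.
static long long cell_dp3(const Str& A, int as, int ae, const Str& B, int bs,
                          int be, const Scheme& S,
                          const std::vector<std::vector<long long>>& Mtab,
                          const ArcSet* arcs) {
  int n = std::max(0, ae - as + 1), m = std::max(0, be - bs + 1);
  if (n == 0 || m == 0) {
    return (n == 0 && m == 0) ? 0 : (S.g + (long long)(n + m) * S.e);
  }
  std::vector<long long> best((size_t)(n + 1) * (m + 1), NEG);
  std::vector<long long> Mm(m + 1), Ix(m + 1), Iy(m + 1),
      pM(m + 1), pX(m + 1), pY(m + 1);
  pM[0] = 0;
  pX[0] = pY[0] = NEG;
  best[0] = 0;
  for (int j = 1; j <= m; j++) {
    pY[j] = S.g + (long long)j * S.e;
    pM[j] = pX[j] = NEG;
    best[j] = pY[j];
  }
  for (int i = 1; i <= n; i++) {
    Mm[0] = Iy[0] = NEG;
    Ix[0] = S.g + (long long)i * S.e;
    best[(size_t)i * (m + 1)] = Ix[0];
    int ai = as - 1 + i;
    int pa = A.endat[ai];
    bool paok = pa > 0 && A.L[pa] >= as;
    int a = A.seq[ai - 1];
    for (int j = 1; j <= m; j++) {
      int bj = bs - 1 + j;
      long long sub = S.nt(a, B.seq[bj - 1]);
      Mm[j] = max3(pM[j - 1], pX[j - 1], pY[j - 1]) + sub;
      Ix[j] = max3(pM[j] + S.g + S.e, pX[j] + S.e, pY[j] + S.g + S.e);
      Iy[j] = max3(Mm[j - 1] + S.g + S.e, Ix[j - 1] + S.g + S.e,
                   Iy[j - 1] + S.e);
      if (paok) {
        int pb = B.endat[bj];
        if (pb > 0 && B.L[pb] >= bs && (!arcs || arcs->count(arc_key(pa, pb)))) {
          long long mv = Mtab[pa][pb];
          if (mv > NEG) {
            long long src =
                best[(size_t)(A.L[pa] - as) * (m + 1) + (B.L[pb] - bs)];
            if (src > NEG && src + mv > Mm[j]) Mm[j] = src + mv;
          }
        }
      }
      best[(size_t)i * (m + 1) + j] = max3(Mm[j], Ix[j], Iy[j]);
    }
    std::swap(Mm, pM);
    std::swap(Ix, pX);
    std::swap(Iy, pY);
  }
  return max3(pM[m], pX[m], pY[m]);
}

static NumericMatrix to_rmat(const std::vector<std::vector<long long>>& t) {
  int nr = (int)t.size(), nc = (int)t[0].size();
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; i++)
    for (int j = 0; j < nc; j++)
      out(i, j) = (t[i][j] <= NEG) ? NA_REAL : (double)t[i][j];
  return out;
}

// [[Rcpp::export]]
List cpp_full_align(List sa, List sb, List sch, bool want_mbar) {
  Str A = make_str(sa), B = make_str(sb);
  Scheme S = make_scheme(sch);
  int nA = A.n, nB = B.n;
  std::vector<std::vector<long long>> M(nA + 1, std::vector<long long>(nB + 1, NEG)),
      Mh(nA + 1, std::vector<long long>(nB + 1, NEG)),
      Ml(nA + 1, std::vector<long long>(nB + 1, NEG)), Mbar;
  if (want_mbar)
    Mbar.assign(nA + 1, std::vector<long long>(nB + 1, NEG));
  for (int ia = 1; ia <= nA; ia++) {
    for (int ib = 1; ib <= nB; ib++) {
      long long mh, ml;
      cell_dp(A, A.L[ia] + 1, A.R[ia] - 1, B, B.L[ib] + 1, B.R[ib] - 1, S, M,
              mh, ml);
      long long sstr = S.bp(A.dn[ia], B.dn[ib]);
      Mh[ia][ib] = sstr + mh;
      Ml[ia][ib] = (ml > NEG) ? sstr + ml : NEG;
      M[ia][ib] = std::max(Mh[ia][ib], Ml[ia][ib]);
    }
    if (want_mbar) {
      for (int ib = 1; ib <= nB; ib++) {
        long long mh, ml;
        cell_dp(A, A.L[ia], A.R[ia], B, B.L[ib], B.R[ib], S, M, mh, ml);
        Mbar[ia][ib] = std::max(mh, ml);
      }
    }
  }
  long long mh, ml;
  cell_dp(A, 1, A.l, B, 1, B.l, S, M, mh, ml);
  Mh[0][0] = mh;
  Ml[0][0] = (ml > NEG) ? ml : NEG;
  M[0][0] = std::max(Mh[0][0], Ml[0][0]);
  List out = List::create(
      _["score_raw"] = (double)M[0][0], _["M"] = to_rmat(M),
      _["Mh"] = to_rmat(Mh), _["Ml"] = to_rmat(Ml));
  if (want_mbar) out["Mbar"] = to_rmat(Mbar);
  return out;
}

struct OPMrec {
  int pa, pb;
  long long m;
  bool alive;
  // when pruned: the dominating (enclosing) OPM. A pruned OPM is hidden
  // only from contexts that strictly contain its dominator, where the
  // dominance argument applies; elsewhere it remains a valid candidate.
  int dom_a = 0, dom_b = 0;
};

static int pairs_within(const Str& A, int a, int b) {
  if (a > b) return 0;
  int c = 0;
  for (int k = 1; k <= A.n; k++)
    if (A.L[k] >= a && A.R[k] <= b) c++;
  return c;
}

// [[Rcpp::export]]
List cpp_sparse_align(List sa, List sb, List sch, bool prune, bool gate) {
  Str A = make_str(sa), B = make_str(sb);
  Scheme S = make_scheme(sch);
  SimCache sim{&A, &B, &S};
  int nA = A.n, nB = B.n;
  std::vector<std::vector<long long>> M(nA + 1, std::vector<long long>(nB + 1, NEG)),
      Mh(nA + 1, std::vector<long long>(nB + 1, NEG)),
      Ml(nA + 1, std::vector<long long>(nB + 1, NEG)),
      Mbar(nA + 1, std::vector<long long>(nB + 1, NEG));
  std::vector<OPMrec> opms;
  long long z_peak = 0, pruned = 0, mh_computed = 0, mh_skipped = 0;
  std::vector<std::vector<double>> prune_log;  // outerA,outerB,innerA,innerB,Ul,Ur,gap

  // visibility of an OPM (possibly tombstoned) within a region
  auto usable_in = [&](const OPMrec& o, int as, int ae, int bs, int be) {
    if (o.alive) return true;
    // hidden only where the dominating OPM is itself a candidate
    return !(A.L[o.dom_a] >= as && A.R[o.dom_a] <= ae &&
             B.L[o.dom_b] >= bs && B.R[o.dom_b] <= be);
  };

  // candidate arc set for a region, drawn from a row list already filtered
  // on the A side
  auto arcs_for = [&](const std::vector<int>& idx, int as, int ae, int bs,
                      int be, ArcSet& out) {
    out.clear();
    for (int t : idx) {
      const OPMrec& o = opms[t];
      if (B.L[o.pb] >= bs && B.R[o.pb] <= be && usable_in(o, as, ae, bs, be)) {
        out.insert(arc_key(o.pa, o.pb));
      }
    }
  };

  ArcSet arcs;

  // returns true when the cell's couple was detected as an OPM
  auto do_cell = [&](int ia, int ib, const std::vector<int>& row_in,
                     const std::vector<int>& row_span) -> bool {
    bool root = (ia == 0);
    int as = A.L[ia] + 1, ae = A.R[ia] - 1, bs = B.L[ib] + 1, be = B.R[ib] - 1;
    long long sstr = root ? 0 : S.bp(A.dn[ia], B.dn[ib]);
    arcs_for(row_in, as, ae, bs, be, arcs);

    long long la = std::max(0, ae - as + 1), lb = std::max(0, be - bs + 1);
    long long mhat = sstr + std::min(la, lb) * S.dmax +
                     (la != lb ? S.g : 0) + llabs(la - lb) * S.e;

    if (arcs.empty()) {
      // no candidate couples: the cell is a pure hairpin-vs-hairpin case
      long long mhv = sstr + sim.score(as, ae, bs, be);
      mh_computed++;
      Mh[ia][ib] = mhv;
      Ml[ia][ib] = NEG;
      M[ia][ib] = mhv;
    } else if (gate) {
      // combined interior optimum; the hairpin similarity is computed
      // separately only when the upper bound cannot rule it out
      long long v = sstr + cell_dp3(A, as, ae, B, bs, be, S, M, &arcs);
      M[ia][ib] = v;
      if (v > mhat) {
        // Mh <= mhat < v, so the optimum uses at least one matched couple
        mh_skipped++;
        Mh[ia][ib] = NEG;
        Ml[ia][ib] = v;
      } else {
        long long mhv = sstr + sim.score(as, ae, bs, be);
        mh_computed++;
        Mh[ia][ib] = mhv;
        Ml[ia][ib] = (mhv < v) ? v : NEG;  // at a tie Ml is not resolved
      }
    } else {
      long long mh, ml;
      cell_dp(A, as, ae, B, bs, be, S, M, mh, ml, &arcs);
      mh_computed++;
      Mh[ia][ib] = sstr + mh;
      Ml[ia][ib] = (ml > NEG) ? sstr + ml : NEG;
      M[ia][ib] = std::max(Mh[ia][ib], Ml[ia][ib]);
    }

    if (root) return false;

    // OPM detection: unrestricted optimum of the spans [l..r] x [l'..r'],
    // with the couple's own matching available as an arc
    int Sas = A.L[ia], Sae = A.R[ia], Sbs = B.L[ib], Sbe = B.R[ib];
    arcs_for(row_span, Sas, Sae, Sbs, Sbe, arcs);
    arcs.insert(arc_key(ia, ib));
    long long mbar = cell_dp3(A, Sas, Sae, B, Sbs, Sbe, S, M, &arcs);
    Mbar[ia][ib] = mbar;

    if (M[ia][ib] >= mbar) {
      opms.push_back({ia, ib, M[ia][ib], true});
      z_peak++;
      if (prune) {
        // victims lie strictly inside on both sides, so the row candidate
        // list already covers the A side
        for (int t : row_in) {
          OPMrec& chi = opms[t];
          if (!chi.alive || chi.pb == ib) continue;
          if (!(B.L[chi.pb] > B.L[ib] && B.R[chi.pb] < B.R[ib])) continue;
          long long lbA = A.L[chi.pa] - A.L[ia] - 1,
                    lbB = B.L[chi.pb] - B.L[ib] - 1;
          long long ldA = A.R[ia] - A.R[chi.pa] - 1,
                    ldB = B.R[ib] - B.R[chi.pb] - 1;
          long long mbA = pairs_within(A, A.L[ia] + 1, A.L[chi.pa] - 1);
          long long mbB = pairs_within(B, B.L[ib] + 1, B.L[chi.pb] - 1);
          long long mdA = pairs_within(A, A.R[chi.pa] + 1, A.R[ia] - 1);
          long long mdB = pairs_within(B, B.R[chi.pb] + 1, B.R[ib] - 1);
          long long Ul = std::max(mbA, mbB) * S.rmax +
                         std::max(lbA, lbB) * (S.dmax - S.g - S.e);
          long long Ur = std::max(mdA, mdB) * S.rmax +
                         std::max(ldA, ldB) * (S.dmax - S.g - S.e);
          // freed-nucleotide guard: on the path through the enclosed OPM,
          // the outer pair's own nucleotides realign as loop sequence; the
          // gap-region bounds above do not account for them
          long long tl = std::max((long long)0,
                                  std::max(S.rowmax[A.seq[A.L[ia] - 1]],
                                           S.rowmax[B.seq[B.L[ib] - 1]]));
          long long tr = std::max((long long)0,
                                  std::max(S.rowmax[A.seq[A.R[ia] - 1]],
                                           S.rowmax[B.seq[B.R[ib] - 1]]));
          long long gap = M[ia][ib] - chi.m;
          if (gap >= Ul + Ur + tl + tr) {
            chi.alive = false;
            chi.dom_a = ia;
            chi.dom_b = ib;
            pruned++;
            prune_log.push_back({(double)ia, (double)ib, (double)chi.pa,
                                 (double)chi.pb, (double)Ul, (double)Ur,
                                 (double)gap});
          }
        }
      }
      return true;
    }
    return false;
  };

  for (int ia = 1; ia <= nA; ia++) {
    std::vector<int> row_in, row_span;
    for (int t = 0; t < (int)opms.size(); t++) {
      if (A.L[opms[t].pa] > A.L[ia] && A.R[opms[t].pa] < A.R[ia]) {
        row_in.push_back(t);
        row_span.push_back(t);
      }
    }
    for (int ib = 1; ib <= nB; ib++) {
      if (do_cell(ia, ib, row_in, row_span)) {
        // OPMs detected in this row (A-side pair == ia) are span candidates
        // for the later cells of the row
        row_span.push_back((int)opms.size() - 1);
      }
    }
  }
  {
    std::vector<int> all_idx(opms.size());
    for (int t = 0; t < (int)opms.size(); t++) all_idx[t] = t;
    do_cell(0, 0, all_idx, all_idx);
  }

  long long z_final = 0;
  for (const OPMrec& o : opms)
    if (o.alive) z_final++;

  int nz = (int)opms.size();
  IntegerMatrix om(nz, 3);
  NumericVector oscore(nz);
  for (int i = 0; i < nz; i++) {
    om(i, 0) = opms[i].pa;
    om(i, 1) = opms[i].pb;
    om(i, 2) = opms[i].alive ? 1 : 0;
    oscore[i] = (double)opms[i].m;
  }
  NumericMatrix plog(prune_log.size(), 7);
  for (size_t i = 0; i < prune_log.size(); i++)
    for (int j = 0; j < 7; j++) plog(i, j) = prune_log[i][j];

  return List::create(
      _["score_raw"] = (double)M[0][0], _["M"] = to_rmat(M),
      _["Mh"] = to_rmat(Mh), _["Ml"] = to_rmat(Ml), _["Mbar"] = to_rmat(Mbar),
      _["opm_pairs"] = om, _["opm_scores"] = oscore, _["prune_log"] = plog,
      _["z_final"] = (double)z_final, _["z_peak"] = (double)z_peak,
      _["opms_pruned"] = (double)pruned,
      _["mh_cells_computed"] = (double)mh_computed,
      _["mh_cells_skipped"] = (double)mh_skipped,
      _["loop_alignments_computed"] = (double)sim.computed);
}

// ---------------------------------------------------------------------------
// Traceback: recovers one optimal alignment from a filled M table by
// re-running, along the optimal path only, a chain decomposition over all
// couples (this reproduces the optimum of either engine exactly, since both
// compute the same integer optimum). Deterministic tie-breaking: the hairpin
// interpretation wins ties against the chain interpretation; chains prefer
// starting fresh over extending, and earlier (smaller right endpoints)
// candidates over later ones.

static std::vector<int> gotoh_trace(const Str& A, int as, int ae, const Str& B,
                                    int bs, int be, const Scheme& S) {
  int n = std::max(0, ae - as + 1), m = std::max(0, be - bs + 1);
  std::vector<int> ops;  // 0 = column, 1 = consume A (gap in B), 2 = consume B
  if (n == 0 && m == 0) return ops;
  if (n == 0) {
    ops.assign(m, 2);
    return ops;
  }
  if (m == 0) {
    ops.assign(n, 1);
    return ops;
  }
  auto id = [&](int i, int j) { return (size_t)i * (m + 1) + j; };
  std::vector<long long> Mm((size_t)(n + 1) * (m + 1), NEG), Ix(Mm), Iy(Mm);
  Mm[0] = 0;
  for (int j = 1; j <= m; j++) Iy[id(0, j)] = S.g + (long long)j * S.e;
  for (int i = 1; i <= n; i++) Ix[id(i, 0)] = S.g + (long long)i * S.e;
  for (int i = 1; i <= n; i++) {
    int a = A.seq[as - 1 + i - 1];
    for (int j = 1; j <= m; j++) {
      int b = B.seq[bs - 1 + j - 1];
      Mm[id(i, j)] = max3(Mm[id(i - 1, j - 1)], Ix[id(i - 1, j - 1)],
                          Iy[id(i - 1, j - 1)]) + S.nt(a, b);
      Ix[id(i, j)] = max3(Mm[id(i - 1, j)] + S.g + S.e, Ix[id(i - 1, j)] + S.e,
                          Iy[id(i - 1, j)] + S.g + S.e);
      Iy[id(i, j)] = max3(Mm[id(i, j - 1)] + S.g + S.e,
                          Ix[id(i, j - 1)] + S.g + S.e, Iy[id(i, j - 1)] + S.e);
    }
  }
  int i = n, j = m, st;
  long long vM = Mm[id(n, m)], vX = Ix[id(n, m)], vY = Iy[id(n, m)];
  st = (vM >= vX && vM >= vY) ? 0 : (vX >= vY ? 1 : 2);
  std::vector<int> rev;
  while (i > 0 || j > 0) {
    if (i == 0) st = 2;
    else if (j == 0) st = 1;
    if (st == 0) {
      rev.push_back(0);
      long long need = Mm[id(i, j)] - S.nt(A.seq[as - 1 + i - 1], B.seq[bs - 1 + j - 1]);
      i--; j--;
      st = (Mm[id(i, j)] == need) ? 0 : (Ix[id(i, j)] == need ? 1 : 2);
    } else if (st == 1) {
      rev.push_back(1);
      long long v = Ix[id(i, j)];
      i--;
      st = (i >= 0 && Mm[id(i, j)] + S.g + S.e == v)
               ? 0 : ((Ix[id(i, j)] + S.e == v) ? 1 : 2);
    } else {
      rev.push_back(2);
      long long v = Iy[id(i, j)];
      j--;
      st = (Mm[id(i, j)] + S.g + S.e == v)
               ? 0 : ((Ix[id(i, j)] + S.g + S.e == v) ? 1 : 2);
    }
  }
  ops.assign(rev.rbegin(), rev.rend());
  return ops;
}

struct TraceCtx {
  const Str *A, *B;
  const Scheme* S;
  SimCache* sim;
  const std::vector<std::vector<long long>>* M;
  std::string ra, rb, sa, sb;
  std::vector<std::pair<int, int>> match;
  long long seqscore = 0;
  bool ok = true;
};

static const char NTCODE[] = "ACGUN";

static void emit_segment(TraceCtx& c, int as, int ae, int bs, int be) {
  std::vector<int> ops = gotoh_trace(*c.A, as, ae, *c.B, bs, be, *c.S);
  int pa = as, pb = bs;
  for (int op : ops) {
    if (op == 0) {
      c.ra += NTCODE[c.A->seq[pa - 1]]; c.sa += '.';
      c.rb += NTCODE[c.B->seq[pb - 1]]; c.sb += '.';
      pa++; pb++;
    } else if (op == 1) {
      c.ra += NTCODE[c.A->seq[pa - 1]]; c.sa += '.';
      c.rb += '-'; c.sb += '-';
      pa++;
    } else {
      c.ra += '-'; c.sa += '-';
      c.rb += NTCODE[c.B->seq[pb - 1]]; c.sb += '.';
      pb++;
    }
  }
  c.seqscore += c.sim->score(as, ae, bs, be);
}

static void trace_cell(TraceCtx& c, int ia, int ib) {
  const Str& A = *c.A;
  const Str& B = *c.B;
  int as = A.L[ia] + 1, ae = A.R[ia] - 1, bs = B.L[ib] + 1, be = B.R[ib] - 1;
  // candidate couples strictly inside, lex (r_A, r_B) order
  std::vector<std::pair<int, int>> E;
  std::vector<int> pasIn, pbsIn;
  for (int p = 1; p <= A.n; p++)
    if (A.L[p] >= as && A.R[p] <= ae) pasIn.push_back(p);
  for (int p = 1; p <= B.n; p++)
    if (B.L[p] >= bs && B.R[p] <= be) pbsIn.push_back(p);
  for (int p : pasIn)
    for (int q : pbsIn)
      if ((*c.M)[p][q] > NEG) E.push_back({p, q});
  size_t k = E.size();
  std::vector<long long> cv(k);
  std::vector<int> pred(k, -1);
  long long bestml = NEG;
  int bestend = -1;
  for (size_t i = 0; i < k; i++) {
    int p = E[i].first, q = E[i].second;
    long long v = c.sim->score(as, A.L[p] - 1, bs, B.L[q] - 1);
    for (size_t j = 0; j < i; j++) {
      int p2 = E[j].first, q2 = E[j].second;
      if (A.R[p2] < A.L[p] && B.R[q2] < B.L[q]) {
        long long cand = cv[j] + c.sim->score(A.R[p2] + 1, A.L[p] - 1,
                                              B.R[q2] + 1, B.L[q] - 1);
        if (cand > v) {
          v = cand;
          pred[i] = (int)j;
        }
      }
    }
    cv[i] = (*c.M)[p][q] + v;
    long long endv = cv[i] + c.sim->score(A.R[p] + 1, ae, B.R[q] + 1, be);
    if (endv > bestml) {
      bestml = endv;
      bestend = (int)i;
    }
  }
  long long mhv = c.sim->score(as, ae, bs, be);
  if (bestend < 0 || mhv >= bestml) {
    emit_segment(c, as, ae, bs, be);
    return;
  }
  std::vector<int> path;
  for (int t = bestend; t >= 0; t = pred[t]) path.push_back(t);
  std::reverse(path.begin(), path.end());
  int prevp = -1, prevq = -1;
  for (size_t s = 0; s < path.size(); s++) {
    int p = E[path[s]].first, q = E[path[s]].second;
    if (s == 0)
      emit_segment(c, as, A.L[p] - 1, bs, B.L[q] - 1);
    else
      emit_segment(c, A.R[prevp] + 1, A.L[p] - 1, B.R[prevq] + 1, B.L[q] - 1);
    c.ra += NTCODE[A.seq[A.L[p] - 1]]; c.sa += '(';
    c.rb += NTCODE[B.seq[B.L[q] - 1]]; c.sb += '(';
    c.match.push_back({p, q});
    trace_cell(c, p, q);
    c.ra += NTCODE[A.seq[A.R[p] - 1]]; c.sa += ')';
    c.rb += NTCODE[B.seq[B.R[q] - 1]]; c.sb += ')';
    prevp = p;
    prevq = q;
  }
  emit_segment(c, A.R[prevp] + 1, ae, B.R[prevq] + 1, be);
}

// [[Rcpp::export]]
List cpp_traceback(List sa, List sb, List sch, NumericMatrix Mtab) {
  Str A = make_str(sa), B = make_str(sb);
  Scheme S = make_scheme(sch);
  SimCache sim{&A, &B, &S};
  std::vector<std::vector<long long>> M(A.n + 1,
                                        std::vector<long long>(B.n + 1, NEG));
  for (int i = 0; i <= A.n; i++)
    for (int j = 0; j <= B.n; j++)
      if (!NumericMatrix::is_na(Mtab(i, j)))
        M[i][j] = (long long)Mtab(i, j);
  TraceCtx c{&A, &B, &S, &sim, &M};
  trace_cell(c, 0, 0);
  long long strscore = 0;
  int nm = (int)c.match.size();
  IntegerMatrix mm(nm, 2);
  for (int i = 0; i < nm; i++) {
    mm(i, 0) = c.match[i].first;
    mm(i, 1) = c.match[i].second;
    strscore += S.bp(A.dn[c.match[i].first], B.dn[c.match[i].second]);
  }
  return List::create(
      _["aligned_a"] = c.ra, _["aligned_b"] = c.rb, _["structure_a"] = c.sa,
      _["structure_b"] = c.sb, _["matching"] = mm,
      _["score_structure_raw"] = (double)strscore,
      _["score_sequence_raw"] = (double)c.seqscore);
}

// [[Rcpp::export]]
List cpp_gotoh(IntegerVector a, IntegerVector b, IntegerMatrix D, int g, int e,
               bool traceback) {
  Str A, B;
  A.seq.assign(a.begin(), a.end());
  A.l = (int)A.seq.size();
  B.seq.assign(b.begin(), b.end());
  B.l = (int)B.seq.size();
  Scheme S;
  S.R25.assign(625, 0);
  S.D5.resize(25);
  for (int i = 0; i < 5; i++)
    for (int j = 0; j < 5; j++) S.D5[i * 5 + j] = D(i, j);
  S.g = g;
  S.e = e;
  S.rmax = S.dmax = 0;
  SimCache sim{&A, &B, &S};
  long long sc = sim.score(1, A.l, 1, B.l);
  if (!traceback) return List::create(_["score"] = (double)sc);
  std::vector<int> ops = gotoh_trace(A, 1, A.l, B, 1, B.l, S);
  return List::create(_["score"] = (double)sc,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
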