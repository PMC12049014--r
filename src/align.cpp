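// Global alignment under 2-piece affine gap penalties.
//
// Two fill orders over the same five matrices (H, E, F, E2, F2):
//   * row-column: the reference Smith-Waterman-Gotoh-style implementation,
//   * diagonal-antidiagonal (r = i + j, t = i): every cell of anti-diagonal r
//     depends only on diagonals r-1 and r-2, so each diagonal is computed as
//     bulk elementwise work on contiguous per-diagonal buffers plus a one-slot
//     lane shift (the abstract form of the SIMD byte-shift).
// Both share one traceback so score and CIGAR agree exactly.

#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

static const int NEG = INT_MIN / 4; // sentinel; survives repeated subtraction

struct Scheme {
  int match, mismatch, po, pe, po2, pe2;
  bool strict; // strict: H max omits E2/F2 (3-term variant)
};

static Scheme scheme_from_list(List s, bool strict) {
  Scheme sc;
  sc.match = as<int>(s["match"]);
  sc.mismatch = as<int>(s["mismatch"]);
  sc.po = as<int>(s["gap_open"]);
  sc.pe = as<int>(s["gap_extend"]);
  sc.po2 = as<int>(s["gap_open2"]);
  sc.pe2 = as<int>(s["gap_extend2"]);
  sc.strict = strict;
  return sc;
}

static std::vector<int> encode_seq(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
    case 'A': v[i] = 0; break;
    case 'C': v[i] = 1; break;
    case 'G': v[i] = 2; break;
    case 'T': v[i] = 3; break;
    default:  v[i] = 4; // N: always scores mismatch
    }
  }
  return v;
}

static inline int mat_score(int a, int b, const Scheme& sc) {
  return (a == b && a != 4) ? sc.match : sc.mismatch;
}

struct DP {
  int Lt, Lq;
  std::vector<int> H, E, F, E2, F2;
  DP(int lt, int lq) : Lt(lt), Lq(lq) {
    size_t n = (size_t)(lt + 1) * (lq + 1);
    H.assign(n, NEG); E.assign(n, NEG); F.assign(n, NEG);
    E2.assign(n, NEG); F2.assign(n, NEG);
  }
  inline size_t ix(int i, int j) const { return (size_t)i * (Lq + 1) + j; }
};

static inline int hmax(int hd, int e, int f, int e2, int f2, bool strict) {
  int m = hd;
  if (e > m) m = e;
  if (f > m) m = f;
  if (!strict) {
    if (e2 > m) m = e2;
    if (f2 > m) m = f2;
  }
  return m;
}

// ---- row-column fill -------------------------------------------------------

static void fill_rowcol(DP& dp, const std::vector<int>& st,
                        const std::vector<int>& sq, const Scheme& sc) {
  const int Lt = dp.Lt, Lq = dp.Lq;
  dp.H[dp.ix(0, 0)] = 0;
  for (int i = 1; i <= Lt; ++i) {
    size_t c = dp.ix(i, 0), u = dp.ix(i - 1, 0);
    dp.E[c]  = std::max(dp.H[u] - sc.po,  dp.E[u])  - sc.pe;
    dp.E2[c] = std::max(dp.H[u] - sc.po2, dp.E2[u]) - sc.pe2;
    dp.H[c]  = hmax(NEG, dp.E[c], NEG, dp.E2[c], NEG, sc.strict);
  }
  for (int j = 1; j <= Lq; ++j) {
    size_t c = dp.ix(0, j), l = dp.ix(0, j - 1);
    dp.F[c]  = std::max(dp.H[l] - sc.po,  dp.F[l])  - sc.pe;
    dp.F2[c] = std::max(dp.H[l] - sc.po2, dp.F2[l]) - sc.pe2;
    dp.H[c]  = hmax(NEG, NEG, dp.F[c], NEG, dp.F2[c], sc.strict);
  }
  for (int i = 1; i <= Lt; ++i) {
    for (int j = 1; j <= Lq; ++j) {
      size_t c = dp.ix(i, j), u = dp.ix(i - 1, j), l = dp.ix(i, j - 1),
             d = dp.ix(i - 1, j - 1);
      dp.E[c]  = std::max(dp.H[u] - sc.po,  dp.E[u])  - sc.pe;
      dp.E2[c] = std::max(dp.H[u] - sc.po2, dp.E2[u]) - sc.pe2;
      dp.F[c]  = std::max(dp.H[l] - sc.po,  dp.F[l])  - sc.pe;
      dp.F2[c] = std::max(dp.H[l] - sc.po2, dp.F2[l]) - sc.pe2;
      int hd = dp.H[d] + mat_score(st[i - 1], sq[j - 1], sc);
      dp.H[c] = hmax(hd, dp.E[c], dp.F[c], dp.E2[c], dp.F2[c], sc.strict);
    }
  }
}

// ---- diagonal-antidiagonal fill --------------------------------------------

// result[0] = fill; result[t] = values[t-1]: the lane-shift contract.
static void lane_shift_buf(const std::vector<int>& v, std::vector<int>& out,
                           int fill) {
  size_t n = v.size();
  if (n == 0) return;
  out[0] = fill;
  for (size_t t = 1; t < n; ++t) out[t] = v[t - 1];
}

static void fill_antidiag(DP& dp, const std::vector<int>& st,
                          const std::vector<int>& sq, const Scheme& sc) {
  const int Lt = dp.Lt, Lq = dp.Lq;
  const size_t W = (size_t)Lt + 1; // buffers indexed by t = i
  std::vector<int> pH(W, NEG), pE(W, NEG), pF(W, NEG), pE2(W, NEG), pF2(W, NEG),
      ppH(W, NEG);
  std::vector<int> cH(W, NEG), cE(W, NEG), cF(W, NEG), cE2(W, NEG), cF2(W, NEG);
  std::vector<int> pH_s(W, NEG), pE_s(W, NEG), pE2_s(W, NEG), ppH_s(W, NEG);

  for (int r = 0; r <= Lt + Lq; ++r) {
    int t_lo = std::max(0, r - Lq), t_hi = std::min(r, Lt);
    std::fill(cH.begin(), cH.end(), NEG);
    std::fill(cE.begin(), cE.end(), NEG);
    std::fill(cF.begin(), cF.end(), NEG);
    std::fill(cE2.begin(), cE2.end(), NEG);
    std::fill(cF2.begin(), cF2.end(), NEG);
    // shift once per diagonal: (r-1, t-1) and (r-2, t-1) neighbours become
    // plain elementwise reads at index t
    lane_shift_buf(pH, pH_s, NEG);
    lane_shift_buf(pE, pE_s, NEG);
    lane_shift_buf(pE2, pE2_s, NEG);
    lane_shift_buf(ppH, ppH_s, NEG);
    for (int t = t_lo; t <= t_hi; ++t) {
      int i = t, j = r - t;
      if (i == 0 && j == 0) {
        cH[t] = 0;
      } else if (j == 0) {
        cE[t]  = std::max(pH_s[t] - sc.po,  pE_s[t])  - sc.pe;
        cE2[t] = std::max(pH_s[t] - sc.po2, pE2_s[t]) - sc.pe2;
        cH[t]  = hmax(NEG, cE[t], NEG, cE2[t], NEG, sc.strict);
      } else if (i == 0) {
        cF[t]  = std::max(pH[t] - sc.po,  pF[t])  - sc.pe;
        cF2[t] = std::max(pH[t] - sc.po2, pF2[t]) - sc.pe2;
        cH[t]  = hmax(NEG, NEG, cF[t], NEG, cF2[t], sc.strict);
      } else {
        cE[t]  = std::max(pH_s[t] - sc.po,  pE_s[t])  - sc.pe;
        cE2[t] = std::max(pH_s[t] - sc.po2, pE2_s[t]) - sc.pe2;
        cF[t]  = std::max(pH[t] - sc.po,  pF[t])  - sc.pe;
        cF2[t] = std::max(pH[t] - sc.po2, pF2[t]) - sc.pe2;
        int hd = ppH_s[t] + mat_score(st[i - 1], sq[j - 1], sc);
        cH[t]  = hmax(hd, cE[t], cF[t], cE2[t], cF2[t], sc.strict);
      }
      size_t c = dp.ix(i, j);
      dp.H[c] = cH[t]; dp.E[c] = cE[t]; dp.F[c] = cF[t];
      dp.E2[c] = cE2[t]; dp.F2[c] = cF2[t];
    }
    ppH.swap(pH);
    pH.swap(cH); pE.swap(cE); pF.swap(cF); pE2.swap(cE2); pF2.swap(cF2);
  }
}

// ---- traceback -------------------------------------------------------------

// Tie-breaking: prefer M over D (E-type) over I (F-type); within a gap state
// prefer extension over re-open. Deterministic CIGARs.
static void traceback(const DP& dp, const std::vector<int>& st,
                      const std::vector<int>& sq, const Scheme& sc,
                      std::vector<int>& lens, std::vector<char>& ops) {
  int i = dp.Lt, j = dp.Lq;
  int state = 0; // 0=H, 1=E, 2=E2, 3=F, 4=F2
  std::vector<char> path; // reversed op stream
  path.reserve(dp.Lt + dp.Lq);
  while (i > 0 || j > 0) {
    size_t c = dp.ix(i, j);
    if (state == 0) {
      int h = dp.H[c];
      if (i > 0 && j > 0 &&
          h == dp.H[dp.ix(i - 1, j - 1)] + mat_score(st[i - 1], sq[j - 1], sc)) {
        path.push_back('M'); --i; --j;
      } else if (i > 0 && h == dp.E[c]) {
        state = 1;
      } else if (!sc.strict && i > 0 && h == dp.E2[c]) {
        state = 2;
      } else if (j > 0 && h == dp.F[c]) {
        state = 3;
      } else if (!sc.strict && j > 0 && h == dp.F2[c]) {
        state = 4;
      } else {
        stop("traceback failed at H(%d,%d)", i, j);
      }
    } else if (state == 1 || state == 2) {
      const std::vector<int>& M = (state == 1) ? dp.E : dp.E2;
      int pe = (state == 1) ? sc.pe : sc.pe2;
      path.push_back('D');
      bool ext = (i > 1) && (M[c] == M[dp.ix(i - 1, j)] - pe);
      --i;
      if (!ext) state = 0;
    } else {
      const std::vector<int>& M = (state == 3) ? dp.F : dp.F2;
      int pe = (state == 3) ? sc.pe : sc.pe2;
      path.push_back('I');
      bool ext = (j > 1) && (M[c] == M[dp.ix(i, j - 1)] - pe);
      --j;
      if (!ext) state = 0;
    }
  }
  // run-length encode in forward order
  lens.clear(); ops.clear();
  for (size_t p = path.size(); p > 0; --p) {
    char op = path[p - 1];
    if (!ops.empty() && ops.back() == op) {
      lens.back() += 1;
    } else {
      ops.push_back(op);
      lens.push_back(1);
    }
  }
}

static List align_impl(std::string target, std::string query, List s,
                       bool strict, bool antidiag) {
  Scheme sc = scheme_from_list(s, strict);
  std::vector<int> st = encode_seq(target), sq = encode_seq(query);
  DP dp((int)st.size(), (int)sq.size());
  if (antidiag) fill_antidiag(dp, st, sq, sc);
  else fill_rowcol(dp, st, sq, sc);
  std::vector<int> lens;
  std::vector<char> ops;
  traceback(dp, st, sq, sc, lens, ops);
  CharacterVector opv(ops.size());
  IntegerVector lenv(lens.size());
  for (size_t q = 0; q < ops.size(); ++q) {
    opv[q] = std::string(1, ops[q]);
    lenv[q] = lens[q];
  }
  return List::create(_["score"] = dp.H[dp.ix(dp.Lt, dp.Lq)],
                      _["cigar_len"] = lenv, _["cigar_op"] = opv);
}

// [[Rcpp::export(name = ".align_rowcol_cpp")]]
List align_rowcol_cpp(std::string target, std::string query, List scheme,
                      bool strict) {
  return align_impl(target, query, scheme, strict, false);
}

// [[Rcpp::export(name = ".align_antidiag_cpp")]]
List align_antidiag_cpp(std::string target, std::string query, List scheme,
                        bool strict) {
  return align_impl(target, query, scheme, strict, true);
}

// Five full matrices for inspection on small inputs (layout-equivalence and
// coordinate-identity tests).
// [[Rcpp::export(name = ".dp_matrices_cpp")]]
List dp_matrices_cpp(std::string target, std::string query, List scheme,
                     bool strict, bool antidiag) {
  Scheme sc = scheme_from_list(scheme, strict);
  std::vector<int> st = encode_seq(target), sq = encode_seq(query);
  DP dp((int)st.size(), (int)sq.size());
  if (antidiag) fill_antidiag(dp, st, sq, sc);
  else fill_rowcol(dp, st, sq, sc);
  int nr = dp.Lt + 1, nc = dp.Lq + 1;
  IntegerMatrix H(nr, nc), E(nr, nc), F(nr, nc), E2(nr, nc), F2(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      size_t c = dp.ix(i, j);
      H(i, j) = dp.H[c]; E(i, j) = dp.E[c]; F(i, j) = dp.F[c];
      E2(i, j) = dp.E2[c]; F2(i, j) = dp.F2[c];
    }
  return List::create(_["H"] = H, _["E"] = E, _["F"] = F, _["E2"] = E2,
                      _["F2"] = F2, _["neg_inf"] = NEG);
}
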