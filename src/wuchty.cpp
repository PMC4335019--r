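// Core dynamic programming and enumeration engine.
//
// Everything here works in integer tenths of kcal/mol (the Vienna convention)
// so that window comparisons are exact.  Positions are 1-based throughout,
// matching the R level and the closed-interval [i,j] notation.
//
// Pair type codes: 0 none, 1 AU, 2 CG, 3 GC, 4 UA, 5 GU, 6 UG.
// Base codes:      0 A, 1 C, 2 G, 3 U, 4 N (never pairs).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <cmath>
#include <map>
#include <algorithm>

using namespace Rcpp;

static const int INF_E = 100000000;   // "infinite" energy, tenths kcal/mol

static inline int addE(int a, int b) {
  if (a >= INF_E || b >= INF_E) return INF_E;
  return a + b;
}

// ---------------------------------------------------------------------------
// big integers (non-negative), base 1e9, little-endian limbs
// ---------------------------------------------------------------------------

struct Big {
  std::vector<uint32_t> d;           // empty == zero
  bool zero() const { return d.empty(); }
};

static const uint64_t BIG_BASE = 1000000000ull;

static Big bigFrom(uint64_t x) {
  Big b;
  while (x > 0) { b.d.push_back((uint32_t)(x % BIG_BASE)); x /= BIG_BASE; }
  return b;
}

static void bigAddTo(Big& a, const Big& b) {
  if (b.zero()) return;
  size_t n = std::max(a.d.size(), b.d.size());
  a.d.resize(n, 0u);
  uint64_t carry = 0;
  for (size_t i = 0; i < n; ++i) {
    uint64_t s = carry + a.d[i] + (i < b.d.size() ? b.d[i] : 0u);
    a.d[i] = (uint32_t)(s % BIG_BASE);
    carry = s / BIG_BASE;
  }
  if (carry) a.d.push_back((uint32_t)carry);
}

static Big bigMul(const Big& a, const Big& b) {
  Big r;
  if (a.zero() || b.zero()) return r;
  r.d.assign(a.d.size() + b.d.size(), 0u);
  for (size_t i = 0; i < a.d.size(); ++i) {
    uint64_t carry = 0;
    for (size_t j = 0; j < b.d.size(); ++j) {
      uint64_t cur = (uint64_t)a.d[i] * b.d[j] + r.d[i + j] + carry;
      r.d[i + j] = (uint32_t)(cur % BIG_BASE);
      carry = cur / BIG_BASE;
    }
    size_t k = i + b.d.size();
    while (carry) {
      uint64_t cur = r.d[k] + carry;
      r.d[k] = (uint32_t)(cur % BIG_BASE);
      carry = cur / BIG_BASE;
      ++k;
    }
  }
  while (!r.d.empty() && r.d.back() == 0u) r.d.pop_back();
  return r;
}

static std::string bigStr(const Big& a) {
  if (a.zero()) return "0";
  std::string s = std::to_string(a.d.back());
  for (size_t i = a.d.size() - 1; i-- > 0; ) {
    std::string limb = std::to_string(a.d[i]);
    s += std::string(9 - limb.size(), '0') + limb;
  }
  return s;
}

// ---------------------------------------------------------------------------
// model / constraints / options
// ---------------------------------------------------------------------------

struct Model {
  int stack[7][7];                   // [outer type][inner type]
  std::vector<int> hairpin, bulge, internal_;  // indexed by loop length
  int maxTab;
  int multiA, multiB, multiC, terminalAU, logCoef;
};

struct Cons {
  std::vector<int> code;             // 1-based; 0 none, 1 x, 2 pair member, 3 probed
  std::vector<int> partner;          // 1-based; 0 none, else forced partner
  std::vector<std::pair<int,int> > forced;
  int maxSpan;                       // 0 = off
};

struct Opts {
  bool noLP, noMB;
  int minhp;
  bool finiteWindow;
  long long maxE;                    // mfe + window, tenths (finite mode)
  double maxStructures;
};

// constraint codes (mirror of R level)
static const int C_NONE = 0, C_UNPAIRED = 1, C_PAIRMEM = 2, C_PROBED = 3;

static Model parseModel(const List& m) {
  Model mo;
  IntegerMatrix st = m["stack"];
  for (int a = 0; a < 7; ++a)
    for (int b = 0; b < 7; ++b) mo.stack[a][b] = INF_E;
  for (int a = 1; a <= 6; ++a)
    for (int b = 1; b <= 6; ++b) mo.stack[a][b] = st(a - 1, b - 1);
  IntegerVector hp = m["hairpin"], bu = m["bulge"], in = m["internal"];
  mo.maxTab = as<int>(m["maxTab"]);
  mo.hairpin.assign(mo.maxTab + 1, INF_E);
  mo.bulge.assign(mo.maxTab + 1, INF_E);
  mo.internal_.assign(mo.maxTab + 1, INF_E);
  for (int l = 1; l <= mo.maxTab; ++l) {
    mo.hairpin[l] = hp[l - 1];
    mo.bulge[l] = bu[l - 1];
    mo.internal_[l] = in[l - 1];
  }
  mo.multiA = as<int>(m["multiA"]);
  mo.multiB = as<int>(m["multiB"]);
  mo.multiC = as<int>(m["multiC"]);
  mo.terminalAU = as<int>(m["terminalAU"]);
  mo.logCoef = as<int>(m["logCoef"]);
  return mo;
}

static Cons parseCons(const List& c, int N) {
  Cons cs;
  IntegerVector code = c["code"];
  cs.code.assign(N + 2, C_NONE);
  cs.partner.assign(N + 2, 0);
  for (int i = 1; i <= N; ++i) cs.code[i] = code[i - 1];
  IntegerMatrix fp = c["forcedPairs"];
  for (int r = 0; r < fp.nrow(); ++r) {
    int a = fp(r, 0), b = fp(r, 1);
    cs.forced.push_back(std::make_pair(a, b));
    cs.partner[a] = b;
    cs.partner[b] = a;
  }
  cs.maxSpan = as<int>(c["maxSpan"]);
  return cs;
}

static Opts parseOpts(const List& o) {
  Opts op;
  op.noLP = as<bool>(o["noLonelyPairs"]);
  op.noMB = as<bool>(o["noMultibranch"]);
  op.minhp = as<int>(o["minHairpin"]);
  double w = as<double>(o["window"]);
  op.finiteWindow = R_finite(w);
  op.maxE = 0;                       // folder sets mfe + window after fill
  op.maxStructures = as<double>(o["maxStructures"]);
  return op;
}

// ---------------------------------------------------------------------------
// folder: sequence + tables + refinement grammar
// ---------------------------------------------------------------------------

// interval types
static const int IV_F = 0, IV_CN = 1, IV_CW = 2, IV_M = 3;

struct Iv { int i, j; int t; };

struct St {
  std::vector<Iv> sig;
  std::vector<std::pair<int,int> > prs;
  long long dgP, dgSig;
};

// child-generation cursor (low-memory mode resumes from here)
struct Cur {
  int phase, k, l, sub;
  Cur() : phase(0), k(0), l(0), sub(0) {}
};

struct Folder {
  int N;
  std::vector<int> s;                // 1-based base codes
  Model mo;
  Cons cs;
  Opts op;

  std::vector<int> Vn, Vw, M, F;     // (N+2)^2, row-major via idx()
  std::vector<char> allow;           // pair (i,j) admissible under hard rules
  std::vector<int> mustCum;          // prefix count of forced-pair members
  int mfeT;                          // tenths; INF_E if infeasible
  bool filled;

  Folder(const IntegerVector& seq, const List& model, const List& cons,
         const List& opts)
    : N(seq.size()), mo(parseModel(model)), op(parseOpts(opts)), filled(false) {
    s.assign(N + 2, 4);
    for (int i = 1; i <= N; ++i) s[i] = seq[i - 1];
    cs = parseCons(cons, N);
    mustCum.assign(N + 2, 0);
    for (int i = 1; i <= N; ++i)
      mustCum[i] = mustCum[i - 1] + (cs.code[i] == C_PAIRMEM ? 1 : 0);
    buildAllowed();
    mfeT = INF_E;
  }

  size_t idx(int i, int j) const { return (size_t)i * (N + 2) + j; }

  int pt(int i, int j) const {
    int a = s[i], b = s[j];
    if (a == 0 && b == 3) return 1;  // AU
    if (a == 1 && b == 2) return 2;  // CG
    if (a == 2 && b == 1) return 3;  // GC
    if (a == 3 && b == 0) return 4;  // UA
    if (a == 2 && b == 3) return 5;  // GU
    if (a == 3 && b == 2) return 6;  // UG
    return 0;
  }
  static bool isWC(int t) { return t >= 1 && t <= 4; }
  int auT(int t) const { return (t == 2 || t == 3) ? 0 : mo.terminalAU; }
  int auP(int i, int j) const { return auT(pt(i, j)); }
  bool probedPair(int i, int j) const {
    return cs.code[i] == C_PROBED || cs.code[j] == C_PROBED;
  }
  bool canUnp(int k) const { return cs.code[k] != C_PAIRMEM; }
  bool regionFree(int a, int b) const {   // no forced-pair member inside
    if (a > b) return true;
    return mustCum[b] - mustCum[a - 1] == 0;
  }

  void buildAllowed() {
    allow.assign((size_t)(N + 2) * (N + 2), 0);
    for (int i = 1; i <= N; ++i)
      for (int j = i + op.minhp + 1; j <= N; ++j) {
        if (pt(i, j) == 0) continue;
        if (cs.code[i] == C_UNPAIRED || cs.code[j] == C_UNPAIRED) continue;
        if (cs.partner[i] != 0 && cs.partner[i] != j) continue;
        if (cs.partner[j] != 0 && cs.partner[j] != i) continue;
        if (cs.maxSpan > 0 && j - i > cs.maxSpan) continue;
        bool cross = false;
        for (size_t f = 0; f < cs.forced.size(); ++f) {
          int a = cs.forced[f].first, b = cs.forced[f].second;
          if ((i < a && a < j && j < b) || (a < i && i < b && b < j)) {
            cross = true; break;
          }
        }
        if (cross) continue;
        allow[idx(i, j)] = 1;
      }
  }

  int extrap(const std::vector<int>& tab, int len) const {
    if (len <= 0) return INF_E;
    if (len <= mo.maxTab) return tab[len];
    if (tab[mo.maxTab] >= INF_E) return INF_E;
    return tab[mo.maxTab] +
      (int)std::lround(mo.logCoef * std::log((double)len / mo.maxTab));
  }
  int hpE(int len) const {
    if (len < op.minhp) return INF_E;
    return extrap(mo.hairpin, len);
  }

  // energy of the loop between closing pair (i,j) and inner pair (k,l);
  // includes terminal AU charges for non-stack loops, none for stacks and
  // single-nucleotide bulges (helix continuation).
  int intLoopE(int i, int j, int k, int l) const {
    int n1 = k - i - 1, n2 = j - l - 1;
    int ti = pt(i, j), tk = pt(k, l);
    if (n1 == 0 && n2 == 0) return mo.stack[ti][tk];
    if (n1 + n2 == 1) return addE(extrap(mo.bulge, 1), mo.stack[ti][tk]);
    if (n1 == 0 || n2 == 0)
      return addE(extrap(mo.bulge, n1 + n2), auT(ti) + auT(tk));
    return addE(extrap(mo.internal_, n1 + n2), auT(ti) + auT(tk));
  }

  int Vat(int i, int j, bool outerWC) const {
    return outerWC ? Vw[idx(i, j)] : Vn[idx(i, j)];
  }
  int Mat(int i, int j) const { return (j < i) ? INF_E : M[idx(i, j)]; }
  int Fat(int i, int j) const { return (j < i) ? 0 : F[idx(i, j)]; }

  // whether the stack (i+1,j-1) under (i,j) is forbidden by the
  // context-dependent probing rule: (i,j) would become a Watson-Crick pair
  // flanked on both sides by Watson-Crick pairs while carrying a probed
  // nucleotide.
  bool stackExcluded(int i, int j, bool outerWC) const {
    int t = pt(i, j);
    return outerWC && isWC(t) && probedPair(i, j) && isWC(pt(i + 1, j - 1));
  }

  int computeV(int i, int j, bool outerWC) {
    if (!allow[idx(i, j)]) return INF_E;
    int t = pt(i, j);
    int best = INF_E;
    if (regionFree(i + 1, j - 1))
      best = std::min(best, addE(hpE(j - i - 1), auT(t)));
    // stack / bulge / interior: inner pair (k,l)
    for (int k = i + 1; k <= j - op.minhp - 2; ++k) {
      if (!regionFree(i + 1, k - 1)) break;
      for (int l = j - 1; l >= k + op.minhp + 1; --l) {
        if (!regionFree(l + 1, j - 1)) break;
        if (!allow[idx(k, l)]) continue;
        if (k == i + 1 && l == j - 1) {           // stack
          if (!stackExcluded(i, j, outerWC)) {
            int inner = Vat(k, l, isWC(t));
            best = std::min(best, addE(mo.stack[t][pt(k, l)], inner));
          }
        } else {
          best = std::min(best, addE(intLoopE(i, j, k, l), Vn[idx(k, l)]));
        }
      }
    }
    if (!op.noMB) {
      // multibranch: rightmost branch (k,l), >=1 further branch in [i+1,k-1]
      for (int k = i + 2; k <= j - op.minhp - 2; ++k) {
        for (int l = k + op.minhp + 1; l <= j - 1; ++l) {
          if (!allow[idx(k, l)]) continue;
          if (!regionFree(l + 1, j - 1)) continue;
          int m = Mat(i + 1, k - 1);
          if (m >= INF_E) continue;
          int cand = addE(m, Vn[idx(k, l)]);
          cand = addE(cand, mo.multiA + mo.multiB + auT(t) + auP(k, l) +
                            mo.multiC * (j - 1 - l));
          best = std::min(best, cand);
        }
      }
    }
    return best;
  }

  int computeM(int i, int j) {
    int best = INF_E;
    if (canUnp(j)) best = addE(Mat(i, j - 1), mo.multiC);
    for (int k = i; k <= j - op.minhp - 1; ++k) {
      if (!allow[idx(k, j)]) continue;
      int br = addE(Vn[idx(k, j)], mo.multiB + auP(k, j));
      if (br >= INF_E) continue;
      if (k == i) {
        best = std::min(best, br);
      } else {
        best = std::min(best, addE(Mat(i, k - 1), br));
        if (regionFree(i, k - 1))
          best = std::min(best, br + mo.multiC * (k - i));
      }
    }
    return best;
  }

  int computeF(int i, int j) {
    int best = INF_E;
    if (canUnp(j)) best = Fat(i, j - 1);
    for (int k = i; k <= j - op.minhp - 1; ++k) {
      if (!allow[idx(k, j)]) continue;
      int v = addE(Vn[idx(k, j)], auP(k, j));
      if (k > i) v = addE(v, Fat(i, k - 1));
      best = std::min(best, v);
    }
    return best;
  }

  void fill() {
    size_t nn = (size_t)(N + 2) * (N + 2);
    Vn.assign(nn, INF_E);
    Vw.assign(nn, INF_E);
    M.assign(nn, INF_E);
    F.assign(nn, 0);
    for (int len = 1; len <= N; ++len) {
      for (int i = 1; i + len - 1 <= N; ++i) {
        int j = i + len - 1;
        if (len >= op.minhp + 2) {
          Vn[idx(i, j)] = computeV(i, j, false);
          Vw[idx(i, j)] = computeV(i, j, true);
        }
        M[idx(i, j)] = computeM(i, j);
        F[idx(i, j)] = computeF(i, j);
      }
    }
    mfeT = (N >= 1) ? F[idx(1, N)] : 0;
    filled = true;
  }

  void adoptTables(const List& tb) {
    IntegerMatrix vn = tb["Vn"], vw = tb["Vw"], m = tb["M"], f = tb["F"];
    size_t nn = (size_t)(N + 2) * (N + 2);
    Vn.assign(nn, INF_E); Vw.assign(nn, INF_E);
    M.assign(nn, INF_E);  F.assign(nn, 0);
    for (int i = 1; i <= N; ++i)
      for (int j = 1; j <= N; ++j) {
        Vn[idx(i, j)] = vn(i - 1, j - 1);
        Vw[idx(i, j)] = vw(i - 1, j - 1);
        M[idx(i, j)] = m(i - 1, j - 1);
        F[idx(i, j)] = f(i - 1, j - 1);
      }
    mfeT = (N >= 1) ? F[idx(1, N)] : 0;
    filled = true;
  }

  long long bound(const Iv& iv) const {
    switch (iv.t) {
      case IV_F:  return Fat(iv.i, iv.j);
      case IV_CN: return Vn[idx(iv.i, iv.j)];
      case IV_CW: return Vw[idx(iv.i, iv.j)];
      default:    return Mat(iv.i, iv.j);
    }
  }

  bool viable(const St& ch) const {
    if (ch.dgP >= INF_E || ch.dgSig >= INF_E) return false;
    if (op.finiteWindow && ch.dgP + ch.dgSig > op.maxE) return false;
    return true;
  }

  bool hasPair(const St& st, int i, int j) const {
    if (i < 1 || j > N) return false;
    for (size_t p = 0; p < st.prs.size(); ++p)
      if (st.prs[p].first == i && st.prs[p].second == j) return true;
    return false;
  }

  // Build the child of `s` obtained by removing the last interval and adding
  // `add1`/`add2` (i fields <= 0 mean absent), pair `np` (np.first>0), and
  // energy increment dE.  Returns viability.
  bool makeChild(const St& s, long long baseSig, const Iv* add1,
                 const Iv* add2, std::pair<int,int> np, long long dE,
                 St& out) const {
    out.sig.assign(s.sig.begin(), s.sig.end() - 1);
    out.prs = s.prs;
    out.dgP = s.dgP + dE;
    out.dgSig = baseSig;
    if (add1) {
      long long b = bound(*add1);
      if (b >= INF_E) return false;
      out.sig.push_back(*add1);
      out.dgSig += b;
    }
    if (add2) {
      long long b = bound(*add2);
      if (b >= INF_E) return false;
      out.sig.push_back(*add2);
      out.dgSig += b;
    }
    if (np.first > 0) out.prs.push_back(np);
    return viable(out);
  }

  // Generate the next viable child of state s (whose last interval is being
  // refined), resuming from cursor c.  Returns false when exhausted.
  // Child order: the j-unpaired child first, then pairing candidates with k
  // ascending (and inner candidates in a fixed documented order).
  bool nextChild(const St& s, Cur& c, St& out) const {
    const Iv iv = s.sig.back();
    const long long baseSig = s.dgSig - bound(iv);
    const int i = iv.i, j = iv.j;

    if (iv.t == IV_F) {
      if (c.phase == 0) {
        c.phase = 1; c.k = i;
        if (canUnp(j)) {
          Iv a = { i, j - 1, IV_F };
          if (makeChild(s, baseSig, (j - 1 >= i) ? &a : NULL, NULL,
                        std::make_pair(0, 0), 0, out))
            return true;
        }
      }
      while (c.k <= j - op.minhp - 1) {
        int k = c.k++;
        if (!allow[idx(k, j)]) continue;
        Iv a = { i, k - 1, IV_F };
        Iv b = { k, j, IV_CN };
        if (makeChild(s, baseSig, (k - 1 >= i) ? &a : NULL, &b,
                      std::make_pair(k, j), auP(k, j), out))
          return true;
      }
      return false;
    }

    if (iv.t == IV_CN || iv.t == IV_CW) {
      const bool ow = (iv.t == IV_CW);
      const int t = pt(i, j);
      const bool hasOuter = hasPair(s, i - 1, j + 1);
      const bool lonelyOK = !op.noLP || hasOuter;

      if (c.phase == 0) {                       // hairpin
        c.phase = 1;
        if (lonelyOK && regionFree(i + 1, j - 1)) {
          long long dE = addE(hpE(j - i - 1), auT(t));
          if (dE < INF_E &&
              makeChild(s, baseSig, NULL, NULL, std::make_pair(0, 0), dE, out))
            return true;
        }
      }
      if (c.phase == 1) {                       // stack
        c.phase = 2; c.k = i + 1; c.l = j - 1;
        int k = i + 1, l = j - 1;
        if (l - k >= op.minhp + 1 && allow[idx(k, l)] &&
            !stackExcluded(i, j, ow)) {
          Iv a = { k, l, isWC(t) ? IV_CW : IV_CN };
          if (makeChild(s, baseSig, &a, NULL, std::make_pair(k, l),
                        mo.stack[t][pt(k, l)], out))
            return true;
        }
      }
      if (c.phase == 2) {                       // bulge / interior
        if (!lonelyOK) { c.phase = 3; c.k = i + 2; c.l = 0; }
        while (c.phase == 2) {
          int k = c.k, l = c.l;
          if (k > j - op.minhp - 2) { c.phase = 3; c.k = i + 2; c.l = 0; break; }
          if (l < k + op.minhp + 1) { c.k = k + 1; c.l = j - 1; continue; }
          c.l = l - 1;                          // advance before tests
          if (k == i + 1 && l == j - 1) continue;        // stack, done above
          if (!regionFree(i + 1, k - 1) || !regionFree(l + 1, j - 1)) continue;
          if (!allow[idx(k, l)]) continue;
          long long dE = intLoopE(i, j, k, l);
          if (dE >= INF_E) continue;
          Iv a = { k, l, IV_CN };
          if (makeChild(s, baseSig, &a, NULL, std::make_pair(k, l), dE, out))
            return true;
        }
      }
      if (c.phase == 3) {                       // multibranch
        if (op.noMB || !lonelyOK) return false;
        while (true) {
          int k = c.k, l = c.l;
          if (k > j - op.minhp - 2) return false;
          if (l == 0) { c.l = k + op.minhp + 1; continue; }
          if (l > j - 1) { c.k = k + 1; c.l = 0; continue; }
          c.l = l + 1;
          if (!allow[idx(k, l)]) continue;
          if (!regionFree(l + 1, j - 1)) continue;
          long long dE = mo.multiA + mo.multiB + auT(t) + auP(k, l) +
                         mo.multiC * (j - 1 - l);
          Iv a = { i + 1, k - 1, IV_M };
          Iv b = { k, l, IV_CN };
          if (makeChild(s, baseSig, &a, &b, std::make_pair(k, l), dE, out))
            return true;
        }
      }
      return false;
    }

    // IV_M
    if (c.phase == 0) {
      c.phase = 1; c.k = i; c.sub = 0;
      if (canUnp(j) && j - 1 >= i) {
        Iv a = { i, j - 1, IV_M };
        if (makeChild(s, baseSig, &a, NULL, std::make_pair(0, 0), mo.multiC,
                      out))
          return true;
      }
    }
    while (c.k <= j - op.minhp - 1) {
      int k = c.k;
      if (!allow[idx(k, j)]) { ++c.k; c.sub = 0; continue; }
      if (c.sub == 0) {                         // (k,j) is the only branch
        c.sub = 1;
        if (k == i || regionFree(i, k - 1)) {
          Iv a = { k, j, IV_CN };
          long long dE = (long long)mo.multiC * (k - i) + mo.multiB + auP(k, j);
          if (makeChild(s, baseSig, &a, NULL, std::make_pair(k, j), dE, out))
            return true;
        }
      }
      if (c.sub == 1) {                         // further branches to the left
        ++c.k; c.sub = 0;
        if (k > i) {
          Iv a = { i, k - 1, IV_M };
          Iv b = { k, j, IV_CN };
          if (makeChild(s, baseSig, &a, &b, std::make_pair(k, j),
                        mo.multiB + auP(k, j), out))
            return true;
        }
      }
    }
    return false;
  }

  St rootState() const {
    St r;
    r.dgP = 0;
    r.dgSig = 0;
    if (N >= 1) {
      Iv iv = { 1, N, IV_F };
      r.sig.push_back(iv);
      r.dgSig = Fat(1, N);
    }
    return r;
  }
};

// ---------------------------------------------------------------------------
// helpers: R <-> C++ state / structure conversion
// ---------------------------------------------------------------------------

static std::string pairsToDb(int N, const std::vector<std::pair<int,int> >& prs) {
  std::string db(N, '.');
  for (size_t p = 0; p < prs.size(); ++p) {
    db[prs[p].first - 1] = '(';
    db[prs[p].second - 1] = ')';
  }
  return db;
}

static St stateFromR(const List& st) {
  St s;
  IntegerMatrix sig = st["sigma"];
  IntegerMatrix prs = st["pairs"];
  for (int r = 0; r < sig.nrow(); ++r) {
    Iv iv = { sig(r, 0), sig(r, 1), sig(r, 2) };
    s.sig.push_back(iv);
  }
  for (int r = 0; r < prs.nrow(); ++r)
    s.prs.push_back(std::make_pair(prs(r, 0), prs(r, 1)));
  s.dgP = (long long)as<double>(st["dgP"]);
  s.dgSig = (long long)as<double>(st["dgSig"]);
  return s;
}

static List stateToR(const St& s) {
  IntegerMatrix sig(s.sig.size(), 3);
  for (size_t r = 0; r < s.sig.size(); ++r) {
    sig(r, 0) = s.sig[r].i; sig(r, 1) = s.sig[r].j; sig(r, 2) = s.sig[r].t;
  }
  IntegerMatrix prs(s.prs.size(), 2);
  for (size_t r = 0; r < s.prs.size(); ++r) {
    prs(r, 0) = s.prs[r].first; prs(r, 1) = s.prs[r].second;
  }
  return List::create(_["sigma"] = sig, _["pairs"] = prs,
                      _["dgP"] = (double)s.dgP, _["dgSig"] = (double)s.dgSig);
}

// ---------------------------------------------------------------------------
// exported: fill
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".wf_fill")]]
List wf_fill(IntegerVector seq, List model, List cons, List opts) {
  Folder fo(seq, model, cons, opts);
  fo.fill();
  int N = fo.N;
  IntegerMatrix vn(N, N), vw(N, N), m(N, N), f(N, N);
  for (int i = 1; i <= N; ++i)
    for (int j = 1; j <= N; ++j) {
      vn(i - 1, j - 1) = fo.Vn[fo.idx(i, j)];
      vw(i - 1, j - 1) = fo.Vw[fo.idx(i, j)];
      m(i - 1, j - 1) = fo.M[fo.idx(i, j)];
      f(i - 1, j - 1) = (j >= i) ? fo.F[fo.idx(i, j)] : 0;
    }
  return List::create(_["Vn"] = vn, _["Vw"] = vw, _["M"] = m, _["F"] = f,
                      _["mfeT"] = fo.mfeT);
}

// ---------------------------------------------------------------------------
// exported: enumeration (stack mode and low-memory mode)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".wf_enumerate")]]
List wf_enumerate(IntegerVector seq, List model, List cons, List opts,
                  bool lowMemory, double windowTenths) {
  Folder fo(seq, model, cons, opts);
  fo.fill();
  if (fo.op.finiteWindow)
    fo.op.maxE = (long long)fo.mfeT + (long long)windowTenths;

  std::vector<std::string> dbs;
  std::vector<int> energies;
  double processed = 0;
  double maxBeforeFirst = 0, maxStore = 0;
  bool truncated = false;

  if (fo.N >= 1 && fo.mfeT < INF_E) {
    if (!lowMemory) {
      std::vector<St> stack;
      stack.push_back(fo.rootState());
      while (!stack.empty()) {
        if (dbs.empty()) {
          if ((double)stack.size() > maxBeforeFirst)
            maxBeforeFirst = (double)stack.size();
        }
        if ((double)stack.size() > maxStore) maxStore = (double)stack.size();
        St s = stack.back();
        stack.pop_back();
        processed += 1;
        if (s.sig.empty()) {
          dbs.push_back(pairsToDb(fo.N, s.prs));
          energies.push_back((int)s.dgP);
          if ((double)dbs.size() >= fo.op.maxStructures) { truncated = true; break; }
          continue;
        }
        Cur c;
        St ch;
        while (fo.nextChild(s, c, ch)) stack.push_back(ch);
      }
    } else {
      struct Frame { St s; Cur c; };
      std::vector<Frame> fs;
      St root = fo.rootState();
      if (root.sig.empty()) {
        dbs.push_back(pairsToDb(fo.N, root.prs));
        energies.push_back((int)root.dgP);
      } else {
        Frame f0; f0.s = root;
        fs.push_back(f0);
      }
      while (!fs.empty()) {
        if (dbs.empty()) {
          if ((double)fs.size() > maxBeforeFirst)
            maxBeforeFirst = (double)fs.size();
        }
        if ((double)fs.size() > maxStore) maxStore = (double)fs.size();
        Frame& f = fs.back();
        St ch;
        if (fo.nextChild(f.s, f.c, ch)) {
          processed += 1;
          if (ch.sig.empty()) {
            dbs.push_back(pairsToDb(fo.N, ch.prs));
            energies.push_back((int)ch.dgP);
            if ((double)dbs.size() >= fo.op.maxStructures) { truncated = true; break; }
          } else {
            Frame nf; nf.s = ch;
            fs.push_back(nf);
          }
        } else {
          fs.pop_back();
        }
      }
    }
  }

  CharacterVector db(dbs.size());
  IntegerVector en(dbs.size());
  for (size_t r = 0; r < dbs.size(); ++r) {
    db[r] = dbs[r];
    en[r] = energies[r];
  }
  return List::create(_["db"] = db, _["energyT"] = en,
                      _["mfeT"] = (fo.mfeT >= INF_E) ? NA_INTEGER : fo.mfeT,
                      _["processed"] = processed,
                      _["maxStatesBeforeFirst"] = maxBeforeFirst,
                      _["maxStates"] = maxStore,
                      _["truncated"] = truncated);
}

// ---------------------------------------------------------------------------
// exported: single-state refinement (drives the parallel workers)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".wf_refine")]]
List wf_refine(List state, List tables, IntegerVector seq, List model,
               List cons, List opts, double windowTenths) {
  Folder fo(seq, model, cons, opts);
  fo.adoptTables(tables);
  if (fo.op.finiteWindow)
    fo.op.maxE = (long long)fo.mfeT + (long long)windowTenths;
  St s = stateFromR(state);
  if (s.sig.empty()) {
    return List::create(_["isLeaf"] = true,
                        _["db"] = pairsToDb(fo.N, s.prs),
                        _["energyT"] = (int)s.dgP,
                        _["children"] = List(0));
  }
  Cur c;
  St ch;
  List kids;
  while (fo.nextChild(s, c, ch)) kids.push_back(stateToR(ch));
  return List::create(_["isLeaf"] = false, _["children"] = kids);
}

// [[Rcpp::export(name = ".wf_root_state")]]
List wf_root_state(IntegerVector seq, List tables, List model, List cons,
                   List opts) {
  Folder fo(seq, model, cons, opts);
  fo.adoptTables(tables);
  return stateToR(fo.rootState());
}

// ---------------------------------------------------------------------------
// exported: structure counting DP (exact, big integer)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".wf_count")]]
String wf_count(IntegerVector seq, List cons, List opts) {
  // dummy energy-free model: counting never evaluates energies
  int N = seq.size();
  if (N < 1) return String("1");
  List dummyModel = List::create(
    _["stack"] = IntegerMatrix(6, 6),
    _["hairpin"] = IntegerVector(3), _["bulge"] = IntegerVector(3),
    _["internal"] = IntegerVector(3), _["maxTab"] = 3,
    _["multiA"] = 0, _["multiB"] = 0, _["multiC"] = 0,
    _["terminalAU"] = 0, _["logCoef"] = 0);
  Folder fo(seq, dummyModel, cons, opts);
  const int minhp = fo.op.minhp;
  const bool noMB = fo.op.noMB;

  size_t nn = (size_t)(N + 2) * (N + 2);
  std::vector<Big> A(nn), Anp(nn), P0(nn), PW(nn);
  Big one = bigFrom(1);

  // A over empty intervals = 1
  for (int i = 1; i <= N + 1; ++i) A[fo.idx(i, i - 1)] = one;

  for (int len = 1; len <= N; ++len) {
    for (int i = 1; i + len - 1 <= N; ++i) {
      int j = i + len - 1;
      // paired counts first (same-span A not needed for P)
      if (len >= minhp + 2 && fo.allow[fo.idx(i, j)]) {
        int t = fo.pt(i, j);
        bool wcClosing = Folder::isWC(t);
        for (int x = 0; x < 2; ++x) {       // x: outer pair WC?
          Big tot;
          if (!noMB) {
            // all interior structures without the (i+1,j-1) pair ...
            bigAddTo(tot, Anp[fo.idx(i + 1, j - 1)]);
            // ... plus structures stacking (i+1,j-1), unless probing forbids
            if (fo.allow[fo.idx(i + 1, j - 1)] &&
                !(x == 1 && Folder::isWC(t) && fo.probedPair(i, j) &&
                  Folder::isWC(fo.pt(i + 1, j - 1)))) {
              bigAddTo(tot, wcClosing ? PW[fo.idx(i + 1, j - 1)]
                                      : P0[fo.idx(i + 1, j - 1)]);
            }
          } else {
            // at most one branch directly inside a closed pair
            if (fo.regionFree(i + 1, j - 1)) bigAddTo(tot, one); // hairpin
            for (int k = i + 1; k <= j - minhp - 2; ++k) {
              if (!fo.regionFree(i + 1, k - 1)) break;
              for (int l = k + minhp + 1; l <= j - 1; ++l) {
                if (!fo.allow[fo.idx(k, l)]) continue;
                if (!fo.regionFree(l + 1, j - 1)) continue;
                if (k == i + 1 && l == j - 1) {
                  if (!(x == 1 && Folder::isWC(t) && fo.probedPair(i, j) &&
                        Folder::isWC(fo.pt(k, l))))
                    bigAddTo(tot, wcClosing ? PW[fo.idx(k, l)]
                                            : P0[fo.idx(k, l)]);
                } else {
                  bigAddTo(tot, P0[fo.idx(k, l)]);
                }
              }
            }
          }
          if (x == 0) P0[fo.idx(i, j)] = tot; else PW[fo.idx(i, j)] = tot;
        }
      }
      // Anp(i,j): structures on [i,j] not containing the pair (i,j) itself
      Big anp;
      if (fo.canUnp(j)) bigAddTo(anp, A[fo.idx(i, j - 1)]);
      for (int k = i + 1; k <= j - minhp - 1; ++k) {
        if (!fo.allow[fo.idx(k, j)]) continue;
        if (P0[fo.idx(k, j)].zero()) continue;
        bigAddTo(anp, bigMul(A[fo.idx(i, k - 1)], P0[fo.idx(k, j)]));
      }
      Anp[fo.idx(i, j)] = anp;
      Big a = anp;
      if (fo.allow[fo.idx(i, j)]) bigAddTo(a, P0[fo.idx(i, j)]);
      A[fo.idx(i, j)] = a;
    }
  }
  return String(bigStr(A[fo.idx(1, N)]));
}

// ---------------------------------------------------------------------------
// exported: free-energy evaluation of complete structures
// ---------------------------------------------------------------------------

static int evalStructureT(const Folder& fo,
                          const std::vector<int>& partner) {
  int N = fo.N;
  long long total = 0;
  // iterate all loops: for each pair, classify its enclosed loop; plus the
  // exterior loop
  for (int i = 1; i <= N; ++i) {
    int j = partner[i];
    if (j <= i) continue;
    // find branches directly inside (i,j)
    std::vector<std::pair<int,int> > br;
    int unp = 0;
    int k = i + 1;
    while (k < j) {
      if (partner[k] > k) { br.push_back(std::make_pair(k, partner[k])); k = partner[k] + 1; }
      else { ++unp; ++k; }
    }
    int t = fo.pt(i, j);
    if (br.empty()) {
      total += addE(fo.hpE(j - i - 1), fo.auT(t));
    } else if (br.size() == 1) {
      total += fo.intLoopE(i, j, br[0].first, br[0].second);
    } else {
      long long e = fo.mo.multiA + (long long)fo.mo.multiB * br.size() +
                    (long long)fo.mo.multiC * unp + fo.auT(t);
      for (size_t b = 0; b < br.size(); ++b)
        e += fo.auP(br[b].first, br[b].second);
      total += e;
    }
    if (total >= INF_E) return INF_E;
  }
  // exterior loop: terminal AU charges only
  int k = 1;
  while (k <= N) {
    if (partner[k] > k) { total += fo.auP(k, partner[k]); k = partner[k] + 1; }
    else ++k;
  }
  return (total >= INF_E) ? INF_E : (int)total;
}

// [[Rcpp::export(name = ".wf_eval")]]
int wf_eval(IntegerVector seq, IntegerMatrix pairs, List model, List opts) {
  List cons = List::create(
    _["code"] = IntegerVector(seq.size()),
    _["forcedPairs"] = IntegerMatrix(0, 2), _["maxSpan"] = 0);
  Folder fo(seq, model, cons, opts);
  std::vector<int> partner(fo.N + 2, 0);
  for (int r = 0; r < pairs.nrow(); ++r) {
    partner[pairs(r, 0)] = pairs(r, 1);
    partner[pairs(r, 1)] = pairs(r, 0);
  }
  return evalStructureT(fo, partner);
}

// [[Rcpp::export(name = ".wf_eval_batch")]]
IntegerVector wf_eval_batch(IntegerVector seq, CharacterVector dbs, List model,
                            List opts) {
  List cons = List::create(
    _["code"] = IntegerVector(seq.size()),
    _["forcedPairs"] = IntegerMatrix(0, 2), _["maxSpan"] = 0);
  Folder fo(seq, model, cons, opts);
  int N = fo.N;
  IntegerVector out(dbs.size());
  std::vector<int> partner(N + 2);
  std::vector<int> stack;
  for (int r = 0; r < dbs.size(); ++r) {
    std::string db = as<std::string>(dbs[r]);
    if ((int)db.size() != N) stop("dot-bracket length mismatch");
    std::fill(partner.begin(), partner.end(), 0);
    stack.clear();
    for (int p = 0; p < N; ++p) {
      if (db[p] == '(') stack.push_back(p + 1);
      else if (db[p] == ')') {
        if (stack.empty()) stop("unbalanced dot-bracket");
        partner[stack.back()] = p + 1;
        partner[p + 1] = stack.back();
        stack.pop_back();
      }
    }
    if (!stack.empty()) stop("unbalanced dot-bracket");
    out[r] = evalStructureT(fo, partner);
  }
  return out;
}

// ---------------------------------------------------------------------------
// exported: brute-force enumeration (test oracle)
// ---------------------------------------------------------------------------

typedef std::vector<std::pair<int,int> > PairList;

struct Brute {
  const Folder& fo;
  std::map<std::pair<int,int>, std::vector<PairList> > memo;
  Brute(const Folder& f) : fo(f) {}

  const std::vector<PairList>& enumInt(int i, int j) {
    std::pair<int,int> key(i, j);
    std::map<std::pair<int,int>, std::vector<PairList> >::iterator it =
      memo.find(key);
    if (it != memo.end()) return it->second;
    std::vector<PairList> res;
    if (j < i) {
      res.push_back(PairList());
    } else {
      if (fo.canUnp(j)) {
        const std::vector<PairList>& sub = enumInt(i, j - 1);
        res.insert(res.end(), sub.begin(), sub.end());
      }
      for (int k = i; k <= j - fo.op.minhp - 1; ++k) {
        if (!fo.allow[fo.idx(k, j)]) continue;
        std::vector<PairList> left = enumInt(i, k - 1);
        std::vector<PairList> inner = enumInt(k + 1, j - 1);
        for (size_t a = 0; a < left.size(); ++a)
          for (size_t b = 0; b < inner.size(); ++b) {
            PairList pl = left[a];
            pl.insert(pl.end(), inner[b].begin(), inner[b].end());
            pl.push_back(std::make_pair(k, j));
            res.push_back(pl);
          }
      }
    }
    return memo.insert(std::make_pair(key, res)).first->second;
  }
};

// does the structure violate the context-dependent probing rule?
static bool probingViolated(const Folder& fo, const std::vector<int>& partner) {
  for (int i = 1; i <= fo.N; ++i) {
    int j = partner[i];
    if (j <= i) continue;
    if (!(fo.cs.code[i] == C_PROBED || fo.cs.code[j] == C_PROBED)) continue;
    if (!Folder::isWC(fo.pt(i, j))) continue;
    if (i - 1 >= 1 && j + 1 <= fo.N && partner[i - 1] == j + 1 &&
        Folder::isWC(fo.pt(i - 1, j + 1)) &&
        partner[i + 1] == j - 1 && Folder::isWC(fo.pt(i + 1, j - 1)))
      return true;
  }
  return false;
}

// [[Rcpp::export(name = ".wf_brute")]]
CharacterVector wf_brute(IntegerVector seq, List cons, List opts) {
  List dummyModel = List::create(
    _["stack"] = IntegerMatrix(6, 6),
    _["hairpin"] = IntegerVector(3), _["bulge"] = IntegerVector(3),
    _["internal"] = IntegerVector(3), _["maxTab"] = 3,
    _["multiA"] = 0, _["multiB"] = 0, _["multiC"] = 0,
    _["terminalAU"] = 0, _["logCoef"] = 0);
  Folder fo(seq, dummyModel, cons, opts);
  Brute br(fo);
  const std::vector<PairList>& all = br.enumInt(1, fo.N);
  std::vector<std::string> keep;
  std::vector<int> partner(fo.N + 2);
  bool anyProbed = false;
  for (int i = 1; i <= fo.N; ++i)
    if (fo.cs.code[i] == C_PROBED) anyProbed = true;
  for (size_t a = 0; a < all.size(); ++a) {
    if (anyProbed) {
      std::fill(partner.begin(), partner.end(), 0);
      for (size_t p = 0; p < all[a].size(); ++p) {
        partner[all[a][p].first] = all[a][p].second;
        partner[all[a][p].second] = all[a][p].first;
      }
      if (probingViolated(fo, partner)) continue;
    }
    keep.push_back(pairsToDb(fo.N, all[a]));
  }
  return wrap(keep);
}

// ---------------------------------------------------------------------------
// small utilities used at the R level
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".wf_db2pairs")]]
IntegerMatrix wf_db2pairs(std::string db) {
  std::vector<int> stack;
  std::vector<std::pair<int,int> > prs;
  for (size_t p = 0; p < db.size(); ++p) {
    if (db[p] == '(') stack.push_back((int)p + 1);
    else if (db[p] == ')') {
      if (stack.empty()) stop("unbalanced dot-bracket string");
      prs.push_back(std::make_pair(stack.back(), (int)p + 1));
      stack.pop_back();
    } else if (db[p] != '.') stop("illegal character in dot-bracket string");
  }
  if (!stack.empty()) stop("unbalanced dot-bracket string");
  std::sort(prs.begin(), prs.end());
  IntegerMatrix out(prs.size(), 2);
  for (size_t r = 0; r < prs.size(); ++r) {
    out(r, 0) = prs[r].first;
    out(r, 1) = prs[r].second;
  }
  return out;
}
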