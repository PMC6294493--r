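// Nearest-neighbor thermodynamic ensemble over pseudoknot-free secondary
// structures: scaled inside (partition function), outside (pair
// probabilities), a constrained inside used for exact motif formation
// probabilities, and MFE with a deterministic traceback.
//
// Conventions: 0-based sequence indices; bases coded A=0 C=1 G=2 U=3 N=4;
// all per-structure weights are scaled by f per nucleotide so that the MFE
// structure has scaled weight ~1 (prevents overflow on kilobase contexts).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

static const double E_INF = 1e9;

struct NNModel {
  std::vector<int> pair_ok;       // 5x5
  std::vector<double> stack;      // 5^4, outer pair (i,j) then inner (i+1,j-1)
  std::vector<double> au;         // 5x5 terminal AU/GU penalty per pair
  std::vector<double> hairpin;    // [0..30] by loop length
  std::vector<double> bulge;      // [0..30]
  std::vector<double> internal_;  // [0..30] by total unpaired
  double asym_coef, asym_max, js_coef;
  double ml_a, ml_b, ml_c;
  int min_hairpin, max_loop;
  double RT;

  bool pairable(int a, int b) const { return pair_ok[a * 5 + b] != 0; }
  double stackE(int a, int b, int c, int d) const {
    return stack[((a * 5 + b) * 5 + c) * 5 + d];
  }
  double auE(int a, int b) const { return au[a * 5 + b]; }
  double hairpinE(int L) const {
    if (L < min_hairpin) return E_INF;
    if (L <= 30) return hairpin[L];
    return hairpin[30] + js_coef * std::log((double)L / 30.0);
  }
  double bulgeE(int L) const {
    if (L <= 30) return bulge[L];
    return bulge[30] + js_coef * std::log((double)L / 30.0);
  }
  double internalE(int n1, int n2) const {
    int nt = n1 + n2;
    double init = (nt <= 30) ? internal_[nt]
                             : internal_[30] + js_coef * std::log((double)nt / 30.0);
    double asym = asym_coef * std::abs(n1 - n2);
    if (asym > asym_max) asym = asym_max;
    return init + asym;
  }
  // interior loop (stack / bulge / internal) connecting outer (i,j), inner (k,l)
  double interiorE(const std::vector<int>& s, int i, int j, int k, int l) const {
    int n1 = k - i - 1, n2 = j - l - 1;
    if (n1 == 0 && n2 == 0) return stackE(s[i], s[j], s[k], s[l]);
    if (n1 == 0 || n2 == 0) {
      int L = n1 + n2;
      if (L == 1) return bulge[1] + stackE(s[i], s[j], s[k], s[l]);
      return bulgeE(L) + auE(s[i], s[j]) + auE(s[k], s[l]);
    }
    return internalE(n1, n2) + auE(s[i], s[j]) + auE(s[k], s[l]);
  }

  // precomputed Boltzmann factors for the hot loops
  std::vector<double> expStack, expAU, expBulge, expInternal, expAsym;
  void buildExpTables() {
    expStack.assign(625, 0.0);
    for (int t = 0; t < 625; ++t)
      if (stack[t] < E_INF / 2) expStack[t] = std::exp(-stack[t] / RT);
    expAU.assign(25, 1.0);
    for (int t = 0; t < 25; ++t) expAU[t] = std::exp(-au[t] / RT);
    expBulge.assign(31, 0.0);
    expInternal.assign(31, 0.0);
    for (int L = 0; L <= 30; ++L) {
      if (bulge[L] < E_INF / 2) expBulge[L] = std::exp(-bulge[L] / RT);
      if (internal_[L] < E_INF / 2) expInternal[L] = std::exp(-internal_[L] / RT);
    }
    expAsym.assign(31, 0.0);
    for (int d = 0; d <= 30; ++d) {
      double a = asym_coef * d;
      if (a > asym_max) a = asym_max;
      expAsym[d] = std::exp(-a / RT);
    }
  }
  // Boltzmann weight of the interior loop (valid for n1+n2 <= max_loop <= 30)
  double interiorW(const std::vector<int>& s, int i, int j, int k, int l) const {
    int n1 = k - i - 1, n2 = j - l - 1;
    size_t os = ((size_t)(s[i] * 5 + s[j]) * 5 + s[k]) * 5 + s[l];
    if (n1 == 0 && n2 == 0) return expStack[os];
    if (n1 == 0 || n2 == 0) {
      int L = n1 + n2;
      if (L == 1) return expBulge[1] * expStack[os];
      return expBulge[L] * expAU[s[i] * 5 + s[j]] * expAU[s[k] * 5 + s[l]];
    }
    return expInternal[n1 + n2] * expAsym[n1 > n2 ? n1 - n2 : n2 - n1] *
           expAU[s[i] * 5 + s[j]] * expAU[s[k] * 5 + s[l]];
  }
};

static NNModel buildModel(const List& m) {
  NNModel M;
  M.pair_ok = as<std::vector<int> >(m["pair_ok"]);
  M.stack = as<std::vector<double> >(m["stack"]);
  M.au = as<std::vector<double> >(m["au"]);
  M.hairpin = as<std::vector<double> >(m["hairpin"]);
  M.bulge = as<std::vector<double> >(m["bulge"]);
  M.internal_ = as<std::vector<double> >(m["internal"]);
  M.asym_coef = as<double>(m["asym_coef"]);
  M.asym_max = as<double>(m["asym_max"]);
  M.js_coef = as<double>(m["js_coef"]);
  M.ml_a = as<double>(m["ml_a"]);
  M.ml_b = as<double>(m["ml_b"]);
  M.ml_c = as<double>(m["ml_c"]);
  M.min_hairpin = as<int>(m["min_hairpin"]);
  M.max_loop = as<int>(m["max_loop"]);
  M.RT = as<double>(m["RT"]);
  M.buildExpTables();
  return M;
}

// ---------------------------------------------------------------- MFE ------

struct MFEArrays {
  int n;
  std::vector<double> V, M, M1, W;  // W has n+1 entries (prefix [0..j-1])
};

static void mfe_fill(const std::vector<int>& s, const NNModel& mod, MFEArrays& A) {
  int n = (int)s.size();
  A.n = n;
  A.V.assign((size_t)n * n, E_INF);
  A.M.assign((size_t)n * n, E_INF);
  A.M1.assign((size_t)n * n, E_INF);
  A.W.assign(n + 1, 0.0);
  int mh = mod.min_hairpin;
  for (int d = mh + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      size_t ij = (size_t)i * n + j;
      if (mod.pairable(s[i], s[j])) {
        double best = mod.hairpinE(j - i - 1) + mod.auE(s[i], s[j]);
        int kmax = std::min(j - 1, i + 1 + mod.max_loop);
        for (int k = i + 1; k <= kmax; ++k) {
          int n1 = k - i - 1;
          int lmin = std::max(k + mh + 1, j - 1 - (mod.max_loop - n1));
          for (int l = lmin; l <= j - 1; ++l) {
            double vkl = A.V[(size_t)k * n + l];
            if (vkl >= E_INF) continue;
            double e = mod.interiorE(s, i, j, k, l) + vkl;
            if (e < best) best = e;
          }
        }
        // multiloop closed by (i,j): >=2 branches inside
        double mlbase = mod.ml_a + mod.ml_b + mod.auE(s[i], s[j]);
        for (int k = i + 2; k <= j - 2; ++k) {
          double m_left = A.M[(size_t)(i + 1) * n + (k - 1)];
          double m1_right = A.M1[(size_t)k * n + (j - 1)];
          if (m_left >= E_INF || m1_right >= E_INF) continue;
          double e = mlbase + m_left + m1_right;
          if (e < best) best = e;
        }
        A.V[ij] = best;
      }
      // M1: last helix starts at i, trailing unpaired to j
      double m1 = E_INF;
      if (j > i) {
        double prev = A.M1[(size_t)i * n + (j - 1)];
        if (prev < E_INF) m1 = prev + mod.ml_c;
      }
      if (A.V[ij] < E_INF) {
        double e = A.V[ij] + mod.ml_b + mod.auE(s[i], s[j]);
        if (e < m1) m1 = e;
      }
      A.M1[ij] = m1;
      // M: >=1 branch, decomposed on start of last branch k
      double m = E_INF;
      for (int k = i; k <= j; ++k) {
        double m1k = A.M1[(size_t)k * n + j];
        if (m1k >= E_INF) continue;
        double before;
        if (k == i) before = 0.0;
        else {
          before = mod.ml_c * (k - i);  // all unpaired
          double mb = A.M[(size_t)i * n + (k - 1)];
          if (mb < before) before = mb;
        }
        double e = before + m1k;
        if (e < m) m = e;
      }
      A.M[ij] = m;
    }
  }
  for (int j = 0; j < n; ++j) {
    double w = A.W[j];  // j unpaired
    for (int k = 0; k <= j - mh - 1; ++k) {
      double v = A.V[(size_t)k * n + j];
      if (v >= E_INF) continue;
      double e = A.W[k] + v + mod.auE(s[k], s[j]);
      if (e < w) w = e;
    }
    A.W[j + 1] = w;
  }
}

static const double TB_EPS = 1e-6;

// deterministic traceback; preference: hairpin, interior (k asc, l desc),
// multiloop (k asc)
static void mfe_traceback(const std::vector<int>& s, const NNModel& mod,
                          const MFEArrays& A, std::string& db) {
  int n = A.n;
  db.assign(n, '.');
  int mh = mod.min_hairpin;
  std::vector<std::vector<int> > todo;  // {state, i, j}; 0=EXT,1=PAIR,2=M,3=M1
  todo.push_back(std::vector<int>{0, 0, n - 1});
  while (!todo.empty()) {
    std::vector<int> t = todo.back();
    todo.pop_back();
    int st = t[0], i = t[1], j = t[2];
    if (st == 0) {  // exterior prefix [0..j]
      while (j >= 0) {
        if (A.W[j + 1] >= A.W[j] - TB_EPS) {  // leaving j unpaired is optimal
          --j;
          continue;
        }
        bool found = false;
        for (int k = 0; k <= j - mh - 1 && !found; ++k) {
          double v = A.V[(size_t)k * n + j];
          if (v >= E_INF) continue;
          if (std::fabs(A.W[k] + v + mod.auE(s[k], s[j]) - A.W[j + 1]) < TB_EPS) {
            db[k] = '('; db[j] = ')';
            todo.push_back(std::vector<int>{1, k, j});
            j = k - 1;
            found = true;
          }
        }
        if (!found) --j;  // fall back: j unpaired
      }
    } else if (st == 1) {  // pair (i,j)
      double target = A.V[(size_t)i * n + j];
      if (std::fabs(mod.hairpinE(j - i - 1) + mod.auE(s[i], s[j]) - target) < TB_EPS)
        continue;
      bool found = false;
      int kmax = std::min(j - 1, i + 1 + mod.max_loop);
      for (int k = i + 1; k <= kmax && !found; ++k) {
        int n1 = k - i - 1;
        int lmin = std::max(k + mh + 1, j - 1 - (mod.max_loop - n1));
        for (int l = j - 1; l >= lmin && !found; --l) {
          double vkl = A.V[(size_t)k * n + l];
          if (vkl >= E_INF) continue;
          if (std::fabs(mod.interiorE(s, i, j, k, l) + vkl - target) < TB_EPS) {
            db[k] = '('; db[l] = ')';
            todo.push_back(std::vector<int>{1, k, l});
            found = true;
          }
        }
      }
      if (found) continue;
      double mlbase = mod.ml_a + mod.ml_b + mod.auE(s[i], s[j]);
      for (int k = i + 2; k <= j - 2 && !found; ++k) {
        double m_left = A.M[(size_t)(i + 1) * n + (k - 1)];
        double m1_right = A.M1[(size_t)k * n + (j - 1)];
        if (m_left >= E_INF || m1_right >= E_INF) continue;
        if (std::fabs(mlbase + m_left + m1_right - target) < TB_EPS) {
          todo.push_back(std::vector<int>{2, i + 1, k - 1});
          todo.push_back(std::vector<int>{3, k, j - 1});
          found = true;
        }
      }
    } else if (st == 3) {  // M1 segment, helix starts at i
      double target = A.M1[(size_t)i * n + j];
      int jj = j;
      while (jj > i) {
        double prev = A.M1[(size_t)i * n + (jj - 1)];
        if (prev < E_INF && std::fabs(prev + mod.ml_c - target) < TB_EPS) {
          target = prev;
          --jj;
        } else break;
      }
      db[i] = '('; db[jj] = ')';
      todo.push_back(std::vector<int>{1, i, jj});
    } else {  // M segment, >=1 branch
      double target = A.M[(size_t)i * n + j];
      bool found = false;
      for (int k = i; k <= j && !found; ++k) {
        double m1k = A.M1[(size_t)k * n + j];
        if (m1k >= E_INF) continue;
        if (k == i) {
          if (std::fabs(m1k - target) < TB_EPS) {
            todo.push_back(std::vector<int>{3, k, j});
            found = true;
          }
        } else {
          if (std::fabs(mod.ml_c * (k - i) + m1k - target) < TB_EPS) {
            todo.push_back(std::vector<int>{3, k, j});
            found = true;
          } else {
            double mb = A.M[(size_t)i * n + (k - 1)];
            if (mb < E_INF && std::fabs(mb + m1k - target) < TB_EPS) {
              todo.push_back(std::vector<int>{2, i, k - 1});
              todo.push_back(std::vector<int>{3, k, j});
              found = true;
            }
          }
        }
      }
    }
  }
}

// ------------------------------------------------------------- inside ------

struct PFArrays {
  int n;
  double f;                      // per-nucleotide scale factor
  std::vector<double> V, QM, QM1;
  std::vector<double> W, WB;     // exterior prefix (n+1) / suffix (n+1)
  double Zs;                     // scaled partition function = W[n]
};

// forced element: pair (fa,fb) with fixed internal structure of energy
// motifE (includes everything inside the footprint); positions fa..fb may
// then appear only through that element.  fa < 0 disables the constraint.
static void pf_inside(const std::vector<int>& s, const NNModel& mod, double f,
                      int fa, int fb, double motifE, PFArrays& A) {
  int n = (int)s.size();
  A.n = n;
  A.f = f;
  A.V.assign((size_t)n * n, 0.0);
  A.QM.assign((size_t)n * n, 0.0);
  A.QM1.assign((size_t)n * n, 0.0);
  A.W.assign(n + 1, 0.0);
  A.WB.assign(n + 1, 0.0);
  int mh = mod.min_hairpin;
  double RT = mod.RT;

  std::vector<double> fpow(n + 2), cfpow(n + 2);
  fpow[0] = 1.0;
  double cf = std::exp(-mod.ml_c / RT) * f;
  cfpow[0] = 1.0;
  for (int t = 1; t <= n + 1; ++t) {
    fpow[t] = fpow[t - 1] * f;
    cfpow[t] = cfpow[t - 1] * cf;
  }
  // prefix count of constrained (footprint) positions < i
  std::vector<int> forb(n + 1, 0);
  for (int i = 0; i < n; ++i)
    forb[i + 1] = forb[i] + ((fa >= 0 && i >= fa && i <= fb) ? 1 : 0);
  // number of footprint positions in [a,b]
  #define NFORB(a, b) ((a) > (b) ? 0 : forb[(b) + 1] - forb[(a)])

  double bfac = std::exp(-mod.ml_b / RT);
  double abW = std::exp(-(mod.ml_a + mod.ml_b) / RT);
  std::vector<double> hw(n + 1, 0.0);  // hairpin Boltzmann weight by loop length
  for (int L = mh; L <= n; ++L) {
    double e = mod.hairpinE(L);
    if (e < E_INF / 2) hw[L] = std::exp(-e / RT);
  }

  for (int d = mh + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      size_t ij = (size_t)i * n + j;
      double v = 0.0;
      bool isForced = (fa >= 0 && i == fa && j == fb);
      bool blocked = false;
      if (fa >= 0 && !isForced) {
        bool iin = (i >= fa && i <= fb), jin = (j >= fa && j <= fb);
        if (iin || jin) blocked = true;
      }
      if (isForced) {
        v = std::exp(-motifE / RT) * fpow[j - i + 1];
      } else if (!blocked && mod.pairable(s[i], s[j])) {
        double auW = mod.expAU[s[i] * 5 + s[j]];
        // hairpin
        if (NFORB(i + 1, j - 1) == 0) {
          v += hw[j - i - 1] * auW * fpow[j - i + 1];
        }
        // interior loops (stack/bulge/internal)
        int kmax = std::min(j - 1, i + 1 + mod.max_loop);
        for (int k = i + 1; k <= kmax; ++k) {
          int n1 = k - i - 1;
          if (NFORB(i + 1, k - 1) > 0) break;  // growing left gap hits footprint
          int lmin = std::max(k + mh + 1, j - 1 - (mod.max_loop - n1));
          for (int l = j - 1; l >= lmin; --l) {
            double vkl = A.V[(size_t)k * n + l];
            if (vkl <= 0.0) continue;
            if (NFORB(l + 1, j - 1) > 0) continue;
            v += mod.interiorW(s, i, j, k, l) * vkl *
                 fpow[(k - i - 1) + (j - l - 1) + 2];
          }
        }
        // multiloop
        double mlfac = abW * auW * fpow[2];
        double msum = 0.0;
        for (int k = i + 2; k <= j - 2; ++k) {
          double qmL = A.QM[(size_t)(i + 1) * n + (k - 1)];
          if (qmL <= 0.0) continue;
          double qm1R = A.QM1[(size_t)k * n + (j - 1)];
          if (qm1R <= 0.0) continue;
          msum += qmL * qm1R;
        }
        v += mlfac * msum;
      }
      A.V[ij] = v;
      // QM1
      double qm1 = 0.0;
      if (j > i) {
        double prev = A.QM1[(size_t)i * n + (j - 1)];
        if (prev > 0.0 && NFORB(j, j) == 0) qm1 = prev * cf;
      }
      if (v > 0.0) qm1 += v * bfac * mod.expAU[s[i] * 5 + s[j]];
      A.QM1[ij] = qm1;
      // QM: decomposed on start of last branch
      double qm = 0.0;
      for (int k = i; k <= j; ++k) {
        double q1 = A.QM1[(size_t)k * n + j];
        if (q1 <= 0.0) continue;
        double before = 0.0;
        if (k == i) before = 1.0;
        else {
          if (NFORB(i, k - 1) == 0) before = cfpow[k - i];
          before += A.QM[(size_t)i * n + (k - 1)];
        }
        qm += before * q1;
      }
      A.QM[ij] = qm;
    }
  }
  // exterior prefix
  A.W[0] = 1.0;
  for (int j = 0; j < n; ++j) {
    double w = (NFORB(j, j) == 0) ? A.W[j] * f : 0.0;
    for (int k = 0; k <= j - mh - 1; ++k) {
      double v = A.V[(size_t)k * n + j];
      if (v <= 0.0) continue;
      w += A.W[k] * v * mod.expAU[s[k] * 5 + s[j]];
    }
    A.W[j + 1] = w;
  }
  A.Zs = A.W[n];
  // exterior suffix (needed by the outside pass)
  A.WB[n] = 1.0;
  for (int i = n - 1; i >= 0; --i) {
    double w = (NFORB(i, i) == 0) ? A.WB[i + 1] * f : 0.0;
    for (int l = i + mh + 1; l < n; ++l) {
      double v = A.V[(size_t)i * n + l];
      if (v <= 0.0) continue;
      w += v * mod.expAU[s[i] * 5 + s[l]] * A.WB[l + 1];
    }
    A.WB[i] = w;
  }
  #undef NFORB
}

static double scale_factor(const std::vector<int>& s, const NNModel& mod,
                           double mfeE) {
  int n = (int)s.size();
  if (n == 0 || mfeE >= 0) return 1.0;
  return std::exp(1.05 * mfeE / (mod.RT * n));
}

// ------------------------------------------------------------ outside ------

// pair probabilities P(i,j) = V(i,j) * Vout(i,j) / Zs
static void pf_outside(const std::vector<int>& s, const NNModel& mod,
                       const PFArrays& A, std::vector<double>& P) {
  int n = A.n;
  double RT = mod.RT;
  double f = A.f;
  int mh = mod.min_hairpin;
  P.assign((size_t)n * n, 0.0);
  if (A.Zs <= 0.0) return;
  std::vector<double> Vout((size_t)n * n, 0.0);
  std::vector<double> Acc((size_t)n * n, 0.0), Bcc((size_t)n * n, 0.0);
  double cf = std::exp(-mod.ml_c / RT) * f;
  std::vector<double> cfpow(n + 2), fpow(n + 2);
  cfpow[0] = 1.0; fpow[0] = 1.0;
  for (int t = 1; t <= n + 1; ++t) {
    cfpow[t] = cfpow[t - 1] * cf;
    fpow[t] = fpow[t - 1] * f;
  }
  double bfac = std::exp(-mod.ml_b / RT);
  double abfac = std::exp(-(mod.ml_a + mod.ml_b) / RT);

  for (int d = n - 1; d >= mh + 1; --d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      size_t ij = (size_t)i * n + j;
      if (A.V[ij] <= 0.0) continue;
      double aufac = mod.expAU[s[i] * 5 + s[j]];
      // exterior
      double vo = A.W[i] * A.WB[j + 1] * aufac;
      // enclosed in an interior loop closed by (k,l)
      int kmin = std::max(0, i - 1 - mod.max_loop);
      for (int k = kmin; k <= i - 1; ++k) {
        int n1 = i - k - 1;
        int lmax = std::min(n - 1, j + 1 + (mod.max_loop - n1));
        for (int l = j + 1; l <= lmax; ++l) {
          double vokl = Vout[(size_t)k * n + l];
          if (vokl <= 0.0) continue;
          if (!mod.pairable(s[k], s[l])) continue;
          vo += vokl * mod.interiorW(s, k, l, i, j) *
                fpow[n1 + (l - j - 1) + 2];
        }
      }
      // branch of a multiloop
      double msum = 0.0;
      for (int k = 0; k <= i - 2; ++k) {
        double qm = A.QM[(size_t)(k + 1) * n + (i - 1)];
        if (qm > 0.0) msum += qm * Acc[(size_t)k * n + j];
      }
      for (int k = 0; k <= i - 1; ++k) {
        double b = Bcc[(size_t)k * n + j];
        if (b > 0.0) msum += cfpow[i - 1 - k] * b;
      }
      vo += bfac * aufac * msum;
      Vout[ij] = vo;
      P[ij] = A.V[ij] * vo / A.Zs;
    }
    // flush this span's contributions into the multiloop accumulators
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      size_t ij = (size_t)i * n + j;
      if (Vout[ij] <= 0.0 || A.V[ij] <= 0.0) continue;
      double O = Vout[ij] * abfac * mod.expAU[s[i] * 5 + s[j]] * fpow[2];
      for (int jj = i + 1; jj <= j - 1; ++jj) {
        double qmR = (jj + 1 <= j - 1) ? A.QM[(size_t)(jj + 1) * n + (j - 1)] : 0.0;
        Acc[(size_t)i * n + jj] += O * (cfpow[j - 1 - jj] + qmR);
        if (qmR > 0.0) Bcc[(size_t)i * n + jj] += O * qmR;
      }
    }
  }
}

// ------------------------------------------------------------ exports ------

// [[Rcpp::export]]
List cpp_mfe(IntegerVector seq, List model) {
  NNModel mod = buildModel(model);
  std::vector<int> s = as<std::vector<int> >(seq);
  int n = (int)s.size();
  if (n < mod.min_hairpin + 2) {
    return List::create(_["structure"] = std::string(n, '.'), _["energy"] = 0.0);
  }
  MFEArrays A;
  mfe_fill(s, mod, A);
  std::string db;
  mfe_traceback(s, mod, A, db);
  return List::create(_["structure"] = db, _["energy"] = A.W[n]);
}

// [[Rcpp::export]]
List cpp_partition(IntegerVector seq, List model, bool want_pairprob) {
  NNModel mod = buildModel(model);
  std::vector<int> s = as<std::vector<int> >(seq);
  int n = (int)s.size();
  if (n < mod.min_hairpin + 2) {
    NumericMatrix pp(n, n);
    return List::create(_["logZ"] = 0.0, _["Zs"] = 1.0, _["scale"] = 1.0,
                        _["pair_prob"] = pp,
                        _["mfe_structure"] = std::string(n, '.'),
                        _["mfe_energy"] = 0.0);
  }
  MFEArrays MA;
  mfe_fill(s, mod, MA);
  std::string db;
  mfe_traceback(s, mod, MA, db);
  double f = scale_factor(s, mod, MA.W[n]);
  PFArrays A;
  pf_inside(s, mod, f, -1, -1, 0.0, A);
  double logZ = std::log(A.Zs) - n * std::log(f);
  List out = List::create(_["logZ"] = logZ, _["Zs"] = A.Zs, _["scale"] = f,
                          _["pair_prob"] = R_NilValue,
                          _["mfe_structure"] = db, _["mfe_energy"] = MA.W[n]);
  if (want_pairprob) {
    std::vector<double> P;
    pf_outside(s, mod, A, P);
    NumericMatrix pp(n, n);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double p = P[(size_t)i * n + j];
        if (p < 0) p = 0;
        if (p > 1) p = 1;
        pp(i, j) = p;
        pp(j, i) = p;
      }
    out["pair_prob"] = pp;
  }
  return out;
}

// Batch version of cpp_pfold: one MFE + one unconstrained inside for the
// whole context, then one constrained inside per motif.
// motifs: 3 columns (a, b inclusive, stem_len).
// [[Rcpp::export]]
NumericVector cpp_pfold_multi(IntegerVector seq, List model, IntegerMatrix motifs) {
  NNModel mod = buildModel(model);
  std::vector<int> s = as<std::vector<int> >(seq);
  int n = (int)s.size();
  int nm = motifs.nrow();
  NumericVector out(nm);
  if (nm == 0) return out;
  MFEArrays MA;
  mfe_fill(s, mod, MA);
  double f = scale_factor(s, mod, MA.W[n]);
  PFArrays U;
  pf_inside(s, mod, f, -1, -1, 0.0, U);
  for (int r = 0; r < nm; ++r) {
    int a = motifs(r, 0), b = motifs(r, 1), stem_len = motifs(r, 2);
    if (a < 0 || b >= n || a >= b) stop("motif coordinates out of range");
    int L = (b - a + 1) - 2 * stem_len;
    double motifE = 0.0;
    bool legal = (L >= mod.min_hairpin);
    for (int k = 0; legal && k < stem_len; ++k) {
      if (!mod.pairable(s[a + k], s[b - k])) legal = false;
      else if (k < stem_len - 1)
        motifE += mod.stackE(s[a + k], s[b - k], s[a + k + 1], s[b - k - 1]);
    }
    if (!legal || U.Zs <= 0.0) { out[r] = 0.0; continue; }
    int ai = a + stem_len - 1, bi = b - stem_len + 1;
    motifE += mod.hairpinE(bi - ai - 1) + mod.auE(s[ai], s[bi]);
    PFArrays C;
    pf_inside(s, mod, f, a, b, motifE, C);
    double p = C.Zs / U.Zs;
    if (p < 0) p = 0;
    if (p > 1) p = 1;
    out[r] = p;
  }
  return out;
}

// Probability that the hairpin element with 5' arm starting at `a`,
// 3' arm ending at `b` (inclusive), `stem_len` pairs and an exact unpaired
// loop between the arms, forms in the full-sequence ensemble.
// [[Rcpp::export]]
double cpp_pfold(IntegerVector seq, List model, int a, int b, int stem_len) {
  NNModel mod = buildModel(model);
  std::vector<int> s = as<std::vector<int> >(seq);
  int n = (int)s.size();
  if (a < 0 || b >= n || a >= b) stop("motif coordinates out of range");
  int L = (b - a + 1) - 2 * stem_len;
  if (L < mod.min_hairpin) return 0.0;
  // all stem pairs must be legal under the model's pairing rule
  double motifE = 0.0;
  for (int k = 0; k < stem_len; ++k) {
    if (!mod.pairable(s[a + k], s[b - k])) return 0.0;
    if (k < stem_len - 1)
      motifE += mod.stackE(s[a + k], s[b - k], s[a + k + 1], s[b - k - 1]);
  }
  int ai = a + stem_len - 1, bi = b - stem_len + 1;  // apical pair
  motifE += mod.hairpinE(bi - ai - 1) + mod.auE(s[ai], s[bi]);
  MFEArrays MA;
  mfe_fill(s, mod, MA);
  double f = scale_factor(s, mod, MA.W[n]);
  PFArrays U, C;
  pf_inside(s, mod, f, -1, -1, 0.0, U);
  if (U.Zs <= 0.0) return 0.0;
  pf_inside(s, mod, f, a, b, motifE, C);
  double p = C.Zs / U.Zs;
  if (p < 0) p = 0;
  if (p > 1) p = 1;
  return p;
}
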