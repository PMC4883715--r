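// Minimum-free-energy folding of a single RNA strand under a simplified
// nearest-neighbor model: stacking energies over the six allowed pairs,
// hairpin/bulge/internal loop penalties by size (interior loops capped),
// and affine multiloops. Energies are integer centi-kcal/mol so optima and
// ties are exact. Secondary objective: among co-optimal structures prefer
// more base pairs; remaining ties are broken by a fixed traceback order.
//
// Recurrences (pseudoknot-free, 0-based, h = min hairpin size):
//   V(i,j)  = min( hairpin(j-i-1),
//                  min_{i<k<l<j} interior(i,j,k,l) + V(k,l),
//                  a + b + min_k M(i+1,k) + M1(k+1,j-1) )   if pairable(i,j)
//   M1(p,q) = min_l V(p,l) + b + (q-l)*c        (helix starts exactly at p)
//   M(p,q)  = min( M(p,q-1)+c, (k-p)*c + V(k,q)+b, M(p,k-1) + V(k,q)+b )
//   W(j)    = min( W(j-1), min_i W(i-1) + V(i,j) ),  W(-1) = 0
#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

static const int INF = INT_MAX / 4;

struct Cell {
  int e;      // energy, centi-kcal
  int pairs;  // number of pairs in the optimal substructure
};

// lexicographic (energy, -pairs) comparison
static inline bool better(int e1, int p1, int e2, int p2) {
  return e1 < e2 || (e1 == e2 && p1 > p2);
}

class Folder {
public:
  std::vector<int> s;              // base codes A=0 C=1 G=2 U=3
  int n, h, maxint;
  int a, b, c;                     // multiloop close/branch/unpaired
  IntegerMatrix stack;             // 6x6, centi-kcal
  IntegerVector hp, bu, il;        // penalties by size, 1-based sizes
  std::vector<Cell> V, M, M1;
  std::vector<Cell> W;

  int idx(int i, int j) const { return i * n + j; }

  int paircode(int i, int j) const {
    static const int tab[4][4] = {
      //        A  C  G  U         (rows = 5' base i, cols = base j)
      /*A*/ { 0, 0, 0, 1 },        // AU = 1
      /*C*/ { 0, 0, 2, 0 },        // CG = 2
      /*G*/ { 0, 3, 0, 5 },        // GC = 3, GU = 5
      /*U*/ { 4, 0, 6, 0 }         // UA = 4, UG = 6
    };
    return tab[s[i]][s[j]];
  }

  int interior_energy(int i, int j, int k, int l) const {
    int n1 = k - i - 1, n2 = j - l - 1;
    if (n1 == 0 && n2 == 0)
      return stack(paircode(i, j) - 1, paircode(k, l) - 1);
    if (n1 == 0 || n2 == 0) return bu[n1 + n2 - 1];
    return il[n1 + n2 - 1];
  }

  void fill() {
    V.assign(n * n, {INF, 0});
    M.assign(n * n, {INF, 0});
    M1.assign(n * n, {INF, 0});
    for (int d = h + 1; d < n; ++d) {
      for (int i = 0; i + d < n; ++i) {
        int j = i + d;
        // ---- V(i,j)
        Cell v = {INF, 0};
        if (paircode(i, j)) {
          int loop = j - i - 1;
          if (loop >= h && loop <= (int)hp.size())
            v = {hp[loop - 1], 1};
          // interior / stack
          for (int k = i + 1; k < j; ++k) {
            int n1 = k - i - 1;
            if (n1 > maxint) break;
            for (int l = j - 1; l > k; --l) {
              int n2 = j - l - 1;
              if (n1 + n2 > maxint) break;
              if (!paircode(k, l)) continue;
              const Cell &in = V[idx(k, l)];
              if (in.e >= INF) continue;
              int e = interior_energy(i, j, k, l) + in.e;
              int p = in.pairs + 1;
              if (better(e, p, v.e, v.pairs)) v = {e, p};
            }
          }
          // multiloop
          for (int k = i + 2; k < j - 1; ++k) {
            const Cell &m = M[idx(i + 1, k)];
            const Cell &m1 = M1[idx(k + 1, j - 1)];
            if (m.e >= INF || m1.e >= INF) continue;
            int e = a + b + m.e + m1.e;
            int p = m.pairs + m1.pairs + 1;
            if (better(e, p, v.e, v.pairs)) v = {e, p};
          }
        }
        V[idx(i, j)] = v;

        // ---- M1(i,j): helix starting exactly at i, trailing unpaired
        Cell m1 = {INF, 0};
        for (int l = i + h + 1; l <= j; ++l) {
          const Cell &vv = V[idx(i, l)];
          if (vv.e >= INF) continue;
          int e = vv.e + b + (j - l) * c;
          if (better(e, vv.pairs, m1.e, m1.pairs)) m1 = {e, vv.pairs};
        }
        M1[idx(i, j)] = m1;

        // ---- M(i,j): >= 1 helix, leading/trailing unpaired allowed
        Cell m = {INF, 0};
        {
          const Cell &prev = M[idx(i, j - 1)];
          if (prev.e < INF) {
            int e = prev.e + c;
            if (better(e, prev.pairs, m.e, m.pairs)) m = {e, prev.pairs};
          }
        }
        for (int k = i; k + h + 1 <= j; ++k) {
          const Cell &vv = V[idx(k, j)];
          if (vv.e >= INF) continue;
          // first helix, (k - i) leading unpaired
          int e = (k - i) * c + vv.e + b;
          if (better(e, vv.pairs, m.e, m.pairs)) m = {e, vv.pairs};
          if (k > i) {
            const Cell &mm = M[idx(i, k - 1)];
            if (mm.e < INF) {
              int e2 = mm.e + vv.e + b;
              int p2 = mm.pairs + vv.pairs;
              if (better(e2, p2, m.e, m.pairs)) m = {e2, p2};
            }
          }
        }
        M[idx(i, j)] = m;
      }
    }
    // ---- external W
    W.assign(n + 1, {0, 0}); // W[t] covers prefix [0, t-1]
    for (int j = 0; j < n; ++j) {
      Cell w = W[j]; // j unpaired
      for (int i = 0; i + h + 1 <= j; ++i) {
        const Cell &vv = V[idx(i, j)];
        if (vv.e >= INF) continue;
        int e = W[i].e + vv.e;
        int p = W[i].pairs + vv.pairs;
        if (better(e, p, w.e, w.pairs)) w = {e, p};
      }
      W[j + 1] = w;
    }
  }

  // ---- traceback (recompute decisions in the fill order) -------------
  std::vector<int> pt; // pair table, -1 = unpaired

  void traceV(int i, int j) {
    const Cell &v = V[idx(i, j)];
    pt[i] = j; pt[j] = i;
    int loop = j - i - 1;
    if (loop >= h && loop <= (int)hp.size() &&
        v.e == hp[loop - 1] && v.pairs == 1)
      return;
    for (int k = i + 1; k < j; ++k) {
      int n1 = k - i - 1;
      if (n1 > maxint) break;
      for (int l = j - 1; l > k; --l) {
        int n2 = j - l - 1;
        if (n1 + n2 > maxint) break;
        if (!paircode(k, l)) continue;
        const Cell &in = V[idx(k, l)];
        if (in.e >= INF) continue;
        if (v.e == interior_energy(i, j, k, l) + in.e &&
            v.pairs == in.pairs + 1) {
          traceV(k, l);
          return;
        }
      }
    }
    for (int k = i + 2; k < j - 1; ++k) {
      const Cell &m = M[idx(i + 1, k)];
      const Cell &m1 = M1[idx(k + 1, j - 1)];
      if (m.e >= INF || m1.e >= INF) continue;
      if (v.e == a + b + m.e + m1.e && v.pairs == m.pairs + m1.pairs + 1) {
        traceM(i + 1, k);
        traceM1(k + 1, j - 1);
        return;
      }
    }
    stop("internal error: V traceback failed");
  }

  void traceM1(int i, int j) {
    const Cell &m1 = M1[idx(i, j)];
    for (int l = i + h + 1; l <= j; ++l) {
      const Cell &vv = V[idx(i, l)];
      if (vv.e >= INF) continue;
      if (m1.e == vv.e + b + (j - l) * c && m1.pairs == vv.pairs) {
        traceV(i, l);
        return;
      }
    }
    stop("internal error: M1 traceback failed");
  }

  void traceM(int i, int j) {
    const Cell &m = M[idx(i, j)];
    if (j > i) {
      const Cell &prev = M[idx(i, j - 1)];
      if (prev.e < INF && m.e == prev.e + c && m.pairs == prev.pairs) {
        traceM(i, j - 1);
        return;
      }
    }
    for (int k = i; k + h + 1 <= j; ++k) {
      const Cell &vv = V[idx(k, j)];
      if (vv.e >= INF) continue;
      if (m.e == (k - i) * c + vv.e + b && m.pairs == vv.pairs) {
        traceV(k, j);
        return;
      }
      if (k > i) {
        const Cell &mm = M[idx(i, k - 1)];
        if (mm.e < INF && m.e == mm.e + vv.e + b &&
            m.pairs == mm.pairs + vv.pairs) {
          traceM(i, k - 1);
          traceV(k, j);
          return;
        }
      }
    }
    stop("internal error: M traceback failed");
  }

  void traceW(int j) { // prefix [0, j-1]
    while (j > 0) {
      const Cell &w = W[j];
      if (w.e == W[j - 1].e && w.pairs == W[j - 1].pairs) {
        --j;
        continue;
      }
      bool found = false;
      for (int i = 0; i + h + 1 <= j - 1; ++i) {
        const Cell &vv = V[idx(i, j - 1)];
        if (vv.e >= INF) continue;
        if (w.e == W[i].e + vv.e && w.pairs == W[i].pairs + vv.pairs) {
          traceV(i, j - 1);
          j = i;
          found = true;
          break;
        }
      }
      if (!found) stop("internal error: W traceback failed");
    }
  }
};

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector seq_codes, IntegerMatrix stack,
                  IntegerVector hairpin, IntegerVector bulge,
                  IntegerVector internal, IntegerVector ml,
                  int min_loop, int max_interior) {
  Folder f;
  f.s = std::vector<int>(seq_codes.begin(), seq_codes.end());
  f.n = f.s.size();
  f.h = min_loop;
  f.maxint = max_interior;
  f.stack = stack;
  f.hp = hairpin; f.bu = bulge; f.il = internal;
  f.a = ml[0]; f.b = ml[1]; f.c = ml[2];

  if (f.n == 0)
    return List::create(_["structure"] = "", _["mfe_cents"] = 0,
                        _["pairs"] = IntegerVector(0));
  f.pt.assign(f.n, -1);
  if (f.n > f.h + 1) {
    f.fill();
    f.traceW(f.n);
  } else {
    f.W.assign(f.n + 1, {0, 0});
  }
  std::string db(f.n, '.');
  for (int i = 0; i < f.n; ++i) {
    if (f.pt[i] > i) db[i] = '(';
    else if (f.pt[i] >= 0) db[i] = ')';
  }
  return List::create(_["structure"] = db,
                      _["mfe_cents"] = f.W[f.n].e,
                      _["pairs"] = f.W[f.n].pairs);
}
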