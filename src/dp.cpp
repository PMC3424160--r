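#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Simplified nearest-neighbour secondary-structure model.
//
// Loop decomposition: every base pair (i,j) closes exactly one loop whose
// energy depends on the pairs immediately interior to it:
//   * no interior pair            -> hairpin loop, flat penalty
//   * one interior pair, no gap   -> helix stack, energy keyed by the outer
//                                    (5'-most) pair type
//   * one interior pair, one-side gap  -> bulge, per-nt penalty
//   * one interior pair, two-side gap  -> internal loop, per-nt penalty
//   * >=2 interior pairs          -> multiloop, charged as an internal loop
//                                    (per unpaired nt inside)
// Exterior (unenclosed) bases are free; the empty structure has energy 0.
//
// Pair-type order for the stack vector: AU UA GC CG GU UG.

static const double INF = std::numeric_limits<double>::infinity();

static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

// AU=0 UA=1 GC=2 CG=3 GU=4 UG=5, -1 if not pairable
static inline int ptype(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

static std::vector<int> encode_seq(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    v[i] = enc(s[i]);
    if (v[i] < 0) stop("invalid nucleotide '%s' at position %d", std::string(1, s[i]), (int)(i + 1));
  }
  return v;
}

struct FoldCtx {
  const std::vector<int>& s;
  const std::vector<double>& stack;
  double hp, bulge, internal_;
  int min_loop, n;
  std::vector<std::vector<double>> V, WM;
  std::vector<double> W;
  std::string db;
  FoldCtx(const std::vector<int>& s_, const std::vector<double>& st,
          double hp_, double bu, double in_, int ml)
    : s(s_), stack(st), hp(hp_), bulge(bu), internal_(in_), min_loop(ml),
      n((int)s_.size()),
      V(n, std::vector<double>(n, INF)), WM(n, std::vector<double>(n, INF)),
      W(n + 1, 0.0), db(n, '.') {}

  inline double loop_cost(int i, int j, int k, int l) const {
    int u1 = k - i - 1, u2 = j - l - 1;
    if (u1 == 0 && u2 == 0) return stack[ptype(s[i], s[j])];
    if (u1 == 0 || u2 == 0) return bulge * (u1 + u2);
    return internal_ * (u1 + u2);
  }

  void fill() {
    for (int span = min_loop + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // V(i,j)
        if (ptype(s[i], s[j]) >= 0) {
          double best = hp;
          for (int k = i + 1; k < j; ++k) {
            for (int l = k + min_loop + 1; l < j; ++l) {
              if (V[k][l] < INF) {
                double e = V[k][l] + loop_cost(i, j, k, l);
                if (e < best) best = e;
              }
            }
          }
          for (int k = i + 2; k < j - 1; ++k) {
            if (WM[i + 1][k] < INF && WM[k + 1][j - 1] < INF) {
              double e = WM[i + 1][k] + WM[k + 1][j - 1];
              if (e < best) best = e;
            }
          }
          V[i][j] = best;
        }
        // WM(i,j): >=1 branch inside a multiloop, unpaired cost internal_/nt
        double wbest = INF;
        if (V[i][j] < INF) wbest = V[i][j];
        if (WM[i + 1][j] < INF && WM[i + 1][j] + internal_ < wbest) wbest = WM[i + 1][j] + internal_;
        if (WM[i][j - 1] < INF && WM[i][j - 1] + internal_ < wbest) wbest = WM[i][j - 1] + internal_;
        for (int k = i; k < j; ++k) {
          if (WM[i][k] < INF && WM[k + 1][j] < INF) {
            double e = WM[i][k] + WM[k + 1][j];
            if (e < wbest) wbest = e;
          }
        }
        WM[i][j] = wbest;
      }
    }
    for (int j = 1; j <= n; ++j) {
      W[j] = W[j - 1];
      for (int i = 0; i <= j - 2; ++i) {
        if (V[i][j - 1] < INF && W[i] + V[i][j - 1] < W[j]) W[j] = W[i] + V[i][j - 1];
      }
    }
  }

  void traceV(int i, int j) {
    db[i] = '('; db[j] = ')';
    if (V[i][j] == hp) return;
    for (int k = i + 1; k < j; ++k)
      for (int l = k + min_loop + 1; l < j; ++l)
        if (V[k][l] < INF && V[k][l] + loop_cost(i, j, k, l) == V[i][j]) {
          traceV(k, l); return;
        }
    for (int k = i + 2; k < j - 1; ++k)
      if (WM[i + 1][k] < INF && WM[k + 1][j - 1] < INF &&
          WM[i + 1][k] + WM[k + 1][j - 1] == V[i][j]) {
        traceWM(i + 1, k); traceWM(k + 1, j - 1); return;
      }
    stop("internal error: fold traceback failed in V");
  }

  void traceWM(int i, int j) {
    if (V[i][j] < INF && V[i][j] == WM[i][j]) { traceV(i, j); return; }
    if (i < j && WM[i + 1][j] < INF && WM[i + 1][j] + internal_ == WM[i][j]) { traceWM(i + 1, j); return; }
    if (i < j && WM[i][j - 1] < INF && WM[i][j - 1] + internal_ == WM[i][j]) { traceWM(i, j - 1); return; }
    for (int k = i; k < j; ++k)
      if (WM[i][k] < INF && WM[k + 1][j] < INF && WM[i][k] + WM[k + 1][j] == WM[i][j]) {
        traceWM(i, k); traceWM(k + 1, j); return;
      }
    stop("internal error: fold traceback failed in WM");
  }

  void traceW(int j) {
    while (j > 0) {
      if (W[j] == W[j - 1]) { --j; continue; }
      bool found = false;
      for (int i = 0; i <= j - 2; ++i) {
        if (V[i][j - 1] < INF && W[i] + V[i][j - 1] == W[j]) {
          traceV(i, j - 1); j = i; found = true; break;
        }
      }
      if (!found) stop("internal error: fold traceback failed in W");
    }
  }
};

// [[Rcpp::export]]
List fold_mfe_cpp(std::string seq, NumericVector stack, double hairpin_penalty,
                  double bulge_per_nt, double internal_per_nt, int min_loop) {
  std::vector<int> s = encode_seq(seq);
  int n = (int)s.size();
  std::vector<double> st(stack.begin(), stack.end());
  if ((int)st.size() != 6) stop("stack energy vector must have 6 entries");
  if (n == 0) return List::create(_["structure"] = "", _["mfe"] = 0.0);
  FoldCtx ctx(s, st, hairpin_penalty, bulge_per_nt, internal_per_nt, min_loop);
  ctx.fill();
  double mfe = ctx.W[n];
  ctx.traceW(n);
  return List::create(_["structure"] = ctx.db, _["mfe"] = mfe);
}

// Intermolecular duplex: monotone antiparallel matching between a miRNA
// (5'->3') and a target window (5'->3'); pair k+1 of the miRNA sits 3' of
// pair k and pairs a window position strictly 5' of pair k's partner.
// Steps between consecutive pairs are charged as stacks (no gap; keyed by
// the 5'-miRNA-side pair), bulges (one-sided gap) or internal loops
// (two-sided gap). The empty duplex has energy 0.

// [[Rcpp::export]]
List duplex_mfe_cpp(std::string mirna, std::string window, NumericVector stack,
                    double bulge_per_nt, double internal_per_nt) {
  std::vector<int> m = encode_seq(mirna), w = encode_seq(window);
  int M = (int)m.size(), Wn = (int)w.size();
  std::vector<double> st(stack.begin(), stack.end());
  if ((int)st.size() != 6) stop("stack energy vector must have 6 entries");
  // D[i][j]: best energy of a duplex whose 3'-most miRNA pair is (i, j)
  std::vector<std::vector<double>> D(M, std::vector<double>(Wn, INF));
  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 0; i < M; ++i) {
    for (int j = 0; j < Wn; ++j) {
      if (ptype(m[i], w[j]) < 0) continue;
      double d = 0.0;  // duplex opened by this single pair
      for (int ip = 0; ip < i; ++ip) {
        for (int jp = j + 1; jp < Wn; ++jp) {
          if (D[ip][jp] == INF) continue;
          int a = i - ip - 1, b = jp - j - 1;
          double cost;
          if (a == 0 && b == 0) cost = st[ptype(m[ip], w[jp])];
          else if (a == 0 || b == 0) cost = bulge_per_nt * (a + b);
          else cost = internal_per_nt * (a + b);
          if (D[ip][jp] + cost < d) d = D[ip][jp] + cost;
        }
      }
      D[i][j] = d;
      if (d < best) { best = d; bi = i; bj = j; }
    }
  }
  // traceback
  std::vector<int> pi, pj;
  if (bi >= 0) {
    int i = bi, j = bj;
    while (true) {
      pi.push_back(i + 1); pj.push_back(j + 1);
      if (D[i][j] == 0.0) break;
      bool found = false;
      for (int ip = 0; ip < i && !found; ++ip) {
        for (int jp = j + 1; jp < Wn && !found; ++jp) {
          if (D[ip][jp] == INF) continue;
          int a = i - ip - 1, b = jp - j - 1;
          double cost;
          if (a == 0 && b == 0) cost = st[ptype(m[ip], w[jp])];
          else if (a == 0 || b == 0) cost = bulge_per_nt * (a + b);
          else cost = internal_per_nt * (a + b);
          if (D[ip][jp] + cost == D[i][j]) { i = ip; j = jp; found = true; }
        }
      }
      if (!found) stop("internal error: duplex traceback failed");
    }
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["energy"] = best,
                      _["mirna_pos"] = IntegerVector(pi.begin(), pi.end()),
                      _["window_pos"] = IntegerVector(pj.begin(), pj.end()));
}
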