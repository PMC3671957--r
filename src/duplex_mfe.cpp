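#include <Rcpp.h>
using namespace Rcpp;

// Intermolecular-only nearest-neighbor MFE dynamic program.
//
// x: transcript window, 5'->3', base codes A=0 C=1 G=2 U=3.
// r: miR reversed (so both strands are scanned left to right; pair
//    (i, k) in (x, r) corresponds to miR position m - k + 1).
// Pairings are sets of pairs strictly increasing in both indices
// (non-crossing, antiparallel). Energy of a non-empty pairing:
//   init + sum over consecutive pairs of either a stack term (adjacent
//   on both strands) or an affine bulge/internal-loop penalty, with the
//   unpaired stretch on each strand capped at max_loop.
// The empty pairing (energy 0) is always admissible.
//
// Ties (within 1e-9) prefer more paired bases, then the chain starting
// 5'-most on the transcript.
//
// stack256: lookup by a*64 + b*16 + c*4 + d for key "ab/cd" (top 5'-ab-3'
// over bottom 3'-cd-5'); entries >= 1e8 mean "no parameter" and the
// stacked step is disallowed.
// [[Rcpp::export]]
List duplex_mfe_cpp(IntegerVector x, IntegerVector r,
                    NumericVector stack256, LogicalVector comp16,
                    double init_penalty, double bulge_open,
                    double bulge_extend, double internal_open,
                    double internal_extend, int max_loop) {
  const int n = x.size(), m = r.size();
  const double INF = 1e18, EPS = 1e-9;
  std::vector<double> H(n * m, INF);
  std::vector<int> NP(n * m, 0), ST(n * m, 0), PI(n * m, -1), PK(n * m, -1);
  auto comp = [&](int a, int b) { return comp16[a * 4 + b]; };
  auto idx = [&](int i, int k) { return i * m + k; };

  int best_cell = -1;
  double best_e = 0.0;  // empty pairing
  int best_np = 0, best_st = n + 1;

  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < m; ++k) {
      if (!comp(x[i], r[k])) continue;
      // chain starting at (i, k)
      double e = init_penalty;
      int np = 1, st = i, pi = -1, pk = -1;
      int i0 = i - 1 - max_loop; if (i0 < 0) i0 = 0;
      int k0 = k - 1 - max_loop; if (k0 < 0) k0 = 0;
      for (int ip = i - 1; ip >= i0; --ip) {
        for (int kp = k - 1; kp >= k0; --kp) {
          int c = idx(ip, kp);
          if (H[c] >= INF) continue;
          int a = i - ip - 1, b = k - kp - 1;
          double step;
          if (a == 0 && b == 0) {
            double s = stack256[x[ip] * 64 + x[i] * 16 + r[kp] * 4 + r[k]];
            if (s >= 1e8) continue;
            step = s;
          } else {
            if (a > max_loop || b > max_loop) continue;
            if (a == 0 || b == 0)
              step = bulge_open + bulge_extend * (a + b - 1);
            else
              step = internal_open + internal_extend * (a + b - 2);
          }
          double cand = H[c] + step;
          int cnp = NP[c] + 1, cst = ST[c];
          if (cand < e - EPS ||
              (cand < e + EPS && (cnp > np ||
                                  (cnp == np && cst < st)))) {
            e = cand; np = cnp; st = cst; pi = ip; pk = kp;
          }
        }
      }
      int c = idx(i, k);
      H[c] = e; NP[c] = np; ST[c] = st; PI[c] = pi; PK[c] = pk;
      if (e < best_e - EPS ||
          (e < best_e + EPS && (np > best_np ||
                                (np == best_np && st < best_st)))) {
        best_e = e; best_np = np; best_st = st; best_cell = c;
      }
    }
  }

  IntegerVector pi_out(best_cell >= 0 ? best_np : 0);
  IntegerVector pk_out(best_cell >= 0 ? best_np : 0);
  if (best_cell >= 0) {
    int c = best_cell;
    for (int t = best_np - 1; t >= 0; --t) {
      pi_out[t] = c / m + 1;  // 1-based
      pk_out[t] = c % m + 1;
      int ni = PI[c], nk = PK[c];
      if (ni < 0) break;
      c = idx(ni, nk);
    }
  }
  double dg = (best_cell >= 0) ? best_e : 0.0;
  if (dg > 0.0 && best_cell >= 0 && dg > EPS) {
    // empty pairing wins over a positive-energy chain
    dg = 0.0;
    pi_out = IntegerVector(0);
    pk_out = IntegerVector(0);
  }
  return List::create(_["dg"] = dg, _["pairs_i"] = pi_out,
                      _["pairs_k"] = pk_out);
}
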