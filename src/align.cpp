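#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap global alignment with free end gaps and position-specific
// gap-open multipliers on the reference axis. Multipliers > 1 inside
// transmembrane segments discourage gaps there, emulating structure-anchored
// alignment. States: M (aligned pair), D (reference residue vs gap in query),
// I (query residue vs gap in reference). Traceback preference at score ties:
// M over D over I, so maps are deterministic.
//
// ref, qry: 1-based integer codes into the substitution matrix.
// mult_del: length n (per reference position, gap-open multiplier for
//           deleting that reference position).
// mult_ins: length n + 1 (gap-open multiplier for inserting query residues
//           after reference position i; index 0 = before the first).
// Returns: score, and map = query index aligned to each reference position
//          (0 where the reference position is gapped).

// [[Rcpp::export]]
List align_affine_cpp(IntegerVector ref, IntegerVector qry,
                      NumericMatrix submat,
                      double gap_open, double gap_ext,
                      NumericVector mult_del, NumericVector mult_ins) {
  const int n = ref.size(), m = qry.size();
  const double NEG = -1e30;
  // DP matrices, (n+1) x (m+1), flattened.
  std::vector<double> M((n + 1) * (m + 1), NEG), D(M), I(M);
  std::vector<unsigned char> tbM(M.size(), 0), tbD(M.size(), 0), tbI(M.size(), 0);
  // traceback codes: predecessor state 1=M, 2=D, 3=I, 0=edge/origin
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) D[at(i, 0)] = 0.0;  // free leading ref gap
  for (int j = 1; j <= m; ++j) I[at(0, j)] = 0.0;  // free leading query gap

  for (int i = 1; i <= n; ++i) {
    const double od = gap_open * mult_del[i - 1] + gap_ext;
    for (int j = 1; j <= m; ++j) {
      const int ij = at(i, j), up = at(i - 1, j), lf = at(i, j - 1),
                dg = at(i - 1, j - 1);
      // M: preference M >= D >= I on ties
      double best = M[dg]; unsigned char tb = 1;
      if (D[dg] > best) { best = D[dg]; tb = 2; }
      if (I[dg] > best) { best = I[dg]; tb = 3; }
      if (best > NEG / 2) {
        M[ij] = best + submat(ref[i - 1] - 1, qry[j - 1] - 1);
        tbM[ij] = tb;
      }
      // D: gap in query at reference position i
      best = M[up] - od; tb = 1;
      if (D[up] - gap_ext > best) { best = D[up] - gap_ext; tb = 2; }
      if (I[up] - od > best) { best = I[up] - od; tb = 3; }
      if (best > NEG / 2) { D[ij] = best; tbD[ij] = tb; }
      // I: gap in reference after position i
      const double oi = gap_open * mult_ins[i] + gap_ext;
      best = M[lf] - oi; tb = 1;
      if (D[lf] - oi > best) { best = D[lf] - oi; tb = 2; }
      if (I[lf] - gap_ext > best) { best = I[lf] - gap_ext; tb = 3; }
      if (best > NEG / 2) { I[ij] = best; tbI[ij] = tb; }
    }
  }
  // Edge rows/cols keep their free-gap zeros; mark their traceback as edge
  // continuation (state itself) so the walk terminates at (0,0) or an edge.

  // Best end: free trailing gaps. Scan last column (j = m) over i, then last
  // row (i = n) over j; strictly-greater updates keep the first maximum.
  double bestScore = NEG; int bi = 0, bj = 0, bs = 0;
  for (int i = 0; i <= n; ++i) {
    const int ij = at(i, m);
    double v = M[ij]; int s = 1;
    if (D[ij] > v) { v = D[ij]; s = 2; }
    if (I[ij] > v) { v = I[ij]; s = 3; }
    if (v > bestScore) { bestScore = v; bi = i; bj = m; bs = s; }
  }
  for (int j = 0; j <= m; ++j) {
    const int ij = at(n, j);
    double v = M[ij]; int s = 1;
    if (D[ij] > v) { v = D[ij]; s = 2; }
    if (I[ij] > v) { v = I[ij]; s = 3; }
    if (v > bestScore) { bestScore = v; bi = n; bj = j; bs = s; }
  }

  IntegerVector map(n, 0);  // query index per reference position, 0 = gap
  int i = bi, j = bj, s = bs;
  while (i > 0 || j > 0) {
    const int ij = at(i, j);
    if (s == 1) {
      if (i == 0 || j == 0) break;  // M only defined at origin on edges
      map[i - 1] = j;
      s = tbM[ij]; --i; --j;
    } else if (s == 2) {
      if (j == 0) { --i; continue; }  // free leading ref gap
      s = tbD[ij]; --i;
    } else {
      if (i == 0) { --j; continue; }  // free leading query gap
      s = tbI[ij]; --j;
    }
  }
  return List::create(_["score"] = bestScore, _["map"] = map);
}
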