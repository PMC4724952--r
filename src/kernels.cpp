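#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment kernels shared by the translated search and the
// protein-guided CDS extraction. A gap of length k costs open + k * ext
// (BLAST convention). Sequences arrive as 0-based integer row indices into
// the substitution matrix.

// Best local alignment score ending at every subject position:
// E[j] = max_i H(i, j). Used to locate hit endpoints on long frames without
// storing the full DP matrix.
// [[Rcpp::export(name = ".sw_best_ends")]]
NumericVector sw_best_ends(IntegerVector q, IntegerVector s,
                           NumericMatrix sub, double gap_open,
                           double gap_ext) {
  const int m = q.size(), n = s.size();
  const int nrow = sub.nrow();
  NumericVector E(n);
  std::vector<double> H(m + 1, 0.0), X(m + 1, R_NegInf);
  const double goe = gap_open + gap_ext;
  const double *subp = REAL(sub);
  const int *qp = INTEGER(q);
  const int *sp = INTEGER(s);
  double *Hp = H.data();
  double *Xp = X.data();
  double best = 0.0;
  for (int j = 1; j <= n; ++j) {
    double diag = Hp[0];   // H(i-1, j-1)
    double y = R_NegInf;   // Y(i, j), gap consuming query
    double colmax = 0.0;
    const double *col = subp + (size_t)sp[j - 1] * nrow;
    for (int i = 1; i <= m; ++i) {
      double x = Hp[i] - goe;
      const double xe = Xp[i] - gap_ext;
      if (xe > x) x = xe;
      Xp[i] = x;
      double yn = Hp[i - 1] - goe;
      const double ye = y - gap_ext;
      if (ye > yn) yn = ye;
      y = yn;
      double h = diag + col[qp[i - 1]];
      if (x > h) h = x;
      if (y > h) h = y;
      if (h < 0.0) h = 0.0;
      diag = Hp[i];
      Hp[i] = h;
      if (h > colmax) colmax = h;
    }
    E[j - 1] = colmax;
    if (colmax > best) best = colmax;
  }
  E.attr("best") = best;
  return E;
}

// Full Smith-Waterman with traceback on a (small) window. Returns the best
// local alignment's score, end coordinates, and column statistics.
// [[Rcpp::export(name = ".sw_traceback")]]
List sw_traceback(IntegerVector q, IntegerVector s, NumericMatrix sub,
                  double gap_open, double gap_ext) {
  const int m = q.size(), n = s.size();
  std::vector<double> H((m + 1) * (n + 1), 0.0), X((m + 1) * (n + 1), R_NegInf),
      Y((m + 1) * (n + 1), R_NegInf);
  // move codes for H: 0 stop, 1 diag, 2 from X (gap in query), 3 from Y
  std::vector<unsigned char> MH((m + 1) * (n + 1), 0), MX((m + 1) * (n + 1), 0),
      MY((m + 1) * (n + 1), 0);
  auto at = [m](int i, int j) { return (size_t)j * (m + 1) + i; };
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int j = 1; j <= n; ++j) {
    for (int i = 1; i <= m; ++i) {
      const size_t c = at(i, j);
      double xo = H[at(i, j - 1)] - gap_open - gap_ext;
      double xe = X[at(i, j - 1)] - gap_ext;
      X[c] = std::max(xo, xe);
      MX[c] = xe > xo ? 1 : 0;  // 1 = extend
      double yo = H[at(i - 1, j)] - gap_open - gap_ext;
      double ye = Y[at(i - 1, j)] - gap_ext;
      Y[c] = std::max(yo, ye);
      MY[c] = ye > yo ? 1 : 0;
      double d = H[at(i - 1, j - 1)] + sub(q[i - 1], s[j - 1]);
      double h = 0.0;
      unsigned char mv = 0;
      if (d > h) { h = d; mv = 1; }
      if (X[c] > h) { h = X[c]; mv = 2; }
      if (Y[c] > h) { h = Y[c]; mv = 3; }
      H[c] = h;
      MH[c] = mv;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj, matches = 0, positives = 0, columns = 0, qres = 0;
  int state = 0;  // 0 = H, 1 = X, 2 = Y
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char mv = MH[at(i, j)];
      if (mv == 0) break;
      if (mv == 1) {
        ++columns;
        ++qres;
        double sc = sub(q[i - 1], s[j - 1]);
        if (q[i - 1] == s[j - 1]) ++matches;
        if (sc > 0) ++positives;
        --i; --j;
      } else if (mv == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {  // gap in query, consume subject
      ++columns;
      state = MX[at(i, j)] ? 1 : 0;
      --j;
    } else {  // gap in subject, consume query
      ++columns;
      ++qres;
      state = MY[at(i, j)] ? 2 : 0;
      --i;
    }
  }
  return List::create(_["score"] = best, _["q_start"] = i + 1,
                      _["q_end"] = bi, _["s_start"] = j + 1, _["s_end"] = bj,
                      _["matches"] = matches, _["positives"] = positives,
                      _["columns"] = columns, _["q_aligned"] = qres);
}

// Frameshift-aware local protein-to-DNA alignment (the Exonerate
// protein2dna analogue). Moves from cell (i residues, j nts):
//   1 codon advance  (+1 aa, +3 nt, substitution score; stop codons take a
//                     fixed penalty and are recorded)
//   2 frameshift -1  (+1 aa, +2 nt, fixed penalty)
//   3 frameshift +1  (+1 aa, +4 nt, fixed penalty)
//   4 residue deletion (+1 aa, +0 nt, affine)
//   5 extra codon in DNA (+0 aa, +3 nt, affine)
// prot: aa row indices; nt: 0..3 or -1 for N; aa_of_codon maps codon index
// (16a+4b+c) to an aa row index; is_stop flags stop codons.
// [[Rcpp::export(name = ".p2d_align")]]
List p2d_align(IntegerVector prot, IntegerVector nt, NumericMatrix sub,
               IntegerVector aa_of_codon, LogicalVector is_stop, int x_idx,
               double fs_pen, double stop_pen, double gap_open,
               double gap_ext) {
  const int m = prot.size(), n = nt.size();
  std::vector<int> caa(n + 1, x_idx);
  std::vector<bool> cstop(n + 1, false);
  for (int j = 3; j <= n; ++j) {
    int a = nt[j - 3], b = nt[j - 2], c = nt[j - 1];
    if (a >= 0 && b >= 0 && c >= 0) {
      int idx = 16 * a + 4 * b + c;
      caa[j] = aa_of_codon[idx];
      cstop[j] = is_stop[idx];
    }
  }
  auto at = [m](int i, int j) { return (size_t)j * (m + 1) + i; };
  std::vector<double> H((m + 1) * (n + 1), 0.0), P((m + 1) * (n + 1), R_NegInf),
      D((m + 1) * (n + 1), R_NegInf);
  // H moves: 0 stop, 1 codon, 2 stop-codon, 3 fs-1, 4 fs+1, 5 from P, 6 from D
  std::vector<unsigned char> MH((m + 1) * (n + 1), 0), MP((m + 1) * (n + 1), 0),
      MD((m + 1) * (n + 1), 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int j = 0; j <= n; ++j) {
    for (int i = 1; i <= m; ++i) {
      const size_t c = at(i, j);
      double po = H[at(i - 1, j)] - gap_open - gap_ext;
      double pe = P[at(i - 1, j)] - gap_ext;
      P[c] = std::max(po, pe);
      MP[c] = pe > po ? 1 : 0;
      if (j >= 3) {
        double doff = H[at(i, j - 3)] - gap_open - gap_ext;
        double de = D[at(i, j - 3)] - gap_ext;
        D[c] = std::max(doff, de);
        MD[c] = de > doff ? 1 : 0;
      }
      double h = 0.0;
      unsigned char mv = 0;
      if (j >= 3) {
        double sc = cstop[j] ? stop_pen
                             : sub(prot[i - 1], caa[j]);
        double d1 = H[at(i - 1, j - 3)] + sc;
        if (d1 > h) { h = d1; mv = cstop[j] ? 2 : 1; }
      }
      if (j >= 2) {
        double d2 = H[at(i - 1, j - 2)] + fs_pen;
        if (d2 > h) { h = d2; mv = 3; }
      }
      if (j >= 4) {
        double d3 = H[at(i - 1, j - 4)] + fs_pen;
        if (d3 > h) { h = d3; mv = 4; }
      }
      if (P[c] > h) { h = P[c]; mv = 5; }
      if (j >= 3 && D[c] > h) { h = D[c]; mv = 6; }
      H[c] = h;
      MH[c] = mv;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback
  std::vector<int> op, ires, jnt;
  int i = bi, j = bj, state = 0;
  while (i > 0) {
    if (state == 0) {
      unsigned char mv = MH[at(i, j)];
      if (mv == 0) break;
      if (mv == 1 || mv == 2) {
        op.push_back(mv);
        ires.push_back(i);
        jnt.push_back(j);
        --i; j -= 3;
      } else if (mv == 3) {
        op.push_back(3); ires.push_back(i); jnt.push_back(j);
        --i; j -= 2;
      } else if (mv == 4) {
        op.push_back(4); ires.push_back(i); jnt.push_back(j);
        --i; j -= 4;
      } else if (mv == 5) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      op.push_back(5); ires.push_back(i); jnt.push_back(j);
      state = MP[at(i, j)] ? 1 : 0;
      --i;
    } else {
      op.push_back(6); ires.push_back(i); jnt.push_back(j);
      state = MD[at(i, j)] ? 2 : 0;
      j -= 3;
    }
  }
  std::reverse(op.begin(), op.end());
  std::reverse(ires.begin(), ires.end());
  std::reverse(jnt.begin(), jnt.end());
  return List::create(_["score"] = best, _["q_start"] = i + 1, _["q_end"] = bi,
                      _["nt_start"] = j + 1, _["nt_end"] = bj,
                      _["op"] = wrap(op), _["ires"] = wrap(ires),
                      _["jnt"] = wrap(jnt));
}
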