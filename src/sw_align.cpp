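#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps, BLAST convention:
// a gap of length k costs open + k * ext.  Sequences arrive pre-encoded as
// 0-based integer indices into the substitution matrix.

// [[Rcpp::export(name = ".sw_scores")]]
NumericVector sw_scores(List qs, List ss, IntegerMatrix pairs,
                        NumericMatrix mat, double open, double ext) {
  int np = pairs.nrow();
  NumericVector out(np);
  double gapo = open + ext;
  for (int p = 0; p < np; ++p) {
    IntegerVector q = qs[pairs(p, 0) - 1];
    IntegerVector s = ss[pairs(p, 1) - 1];
    int n = q.size(), m = s.size();
    if (n == 0 || m == 0) { out[p] = 0.0; continue; }
    // rolling rows of the three states (M match, X gap-in-subject,
    // Y gap-in-query), previous row i-1 and current row i
    const double NEG = -1e300;
    std::vector<double> Mp(m + 1, 0.0), Xp(m + 1, NEG), Yp(m + 1, NEG);
    std::vector<double> Mc(m + 1, 0.0), Xc(m + 1, NEG), Yc(m + 1, NEG);
    const int *qp = q.begin(), *sp = s.begin();
    const double *matp = mat.begin();
    const int nr = mat.nrow();
    double best = 0.0;
    for (int i = 1; i <= n; ++i) {
      const double *mrow = matp + (size_t)qp[i - 1];
      Mc[0] = 0.0; Xc[0] = NEG; Yc[0] = NEG;
      double yprev = NEG, mprev = 0.0;
      for (int j = 1; j <= m; ++j) {
        double x = std::max(Mp[j] - gapo, Xp[j] - ext);
        double y = std::max(mprev - gapo, yprev - ext);
        double d = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
        double v = std::max(0.0, d) + mrow[(size_t)sp[j - 1] * nr];
        if (v < 0) v = 0;
        Mc[j] = v; Xc[j] = x; Yc[j] = y;
        mprev = v; yprev = y;
        if (v > best) best = v;
      }
      std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    }
    out[p] = best;
  }
  return out;
}

// Full alignment with traceback.
// Returns list(score, qstart, qend, sstart, send, nmatch, length,
//              qcols, scols) -- qcols/scols are 1-based positions per
// alignment column, 0 marking a gap.
// [[Rcpp::export(name = ".sw_full")]]
List sw_full(IntegerVector q, IntegerVector s,
             NumericMatrix mat, double open, double ext) {
  int n = q.size(), m = s.size();
  double gapo = open + ext;
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0, _["qstart"] = 0, _["qend"] = 0,
                        _["sstart"] = 0, _["send"] = 0, _["nmatch"] = 0,
                        _["length"] = 0, _["qcols"] = IntegerVector(0),
                        _["scols"] = IntegerVector(0));
  // rolling score rows; full matrices only for the packed traceback codes
  // (bits 0-1: M predecessor 0 start / 1 M / 2 X / 3 Y;
  //  bit 2: X extends X; bit 3: Y extends Y)
  const double NEG = -1e300;
  int W = m + 1;
  std::vector<double> Mp(W, 0.0), Xp(W, NEG), Yp(W, NEG);
  std::vector<double> Mc(W, 0.0), Xc(W, NEG), Yc(W, NEG);
  std::vector<unsigned char> tb((size_t)(n + 1) * W, 0);
  const int *qp = q.begin(), *sp = s.begin();
  const double *matp = mat.begin();
  const int nr = mat.nrow();
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Mc[0] = 0.0; Xc[0] = NEG; Yc[0] = NEG;
    unsigned char *tbrow = &tb[(size_t)i * W];
    const double *mrow = matp + (size_t)qp[i - 1];
    double mprev = 0.0, yprev = NEG;
    for (int j = 1; j <= m; ++j) {
      unsigned char code = 0;
      // X: gap in subject (consumes query)
      double xm = Mp[j] - gapo, xx = Xp[j] - ext;
      double x;
      if (xm >= xx) { x = xm; } else { x = xx; code |= 4; }
      // Y: gap in query (consumes subject)
      double ym = mprev - gapo, yy = yprev - ext;
      double y;
      if (ym >= yy) { y = ym; } else { y = yy; code |= 8; }
      // M
      double cand = 0.0; unsigned char mcode = 0;
      if (Mp[j - 1] > cand) { cand = Mp[j - 1]; mcode = 1; }
      if (Xp[j - 1] > cand) { cand = Xp[j - 1]; mcode = 2; }
      if (Yp[j - 1] > cand) { cand = Yp[j - 1]; mcode = 3; }
      double v = cand + mrow[(size_t)sp[j - 1] * nr];
      if (v < 0) { v = 0; mcode = 0; }
      Mc[j] = v; Xc[j] = x; Yc[j] = y;
      tbrow[j] = code | mcode;
      mprev = v; yprev = y;
      if (v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["qstart"] = 0, _["qend"] = 0,
                        _["sstart"] = 0, _["send"] = 0, _["nmatch"] = 0,
                        _["length"] = 0, _["qcols"] = IntegerVector(0),
                        _["scols"] = IntegerVector(0));
  // traceback from (bi, bj) in state M
  std::vector<int> qc, sc2;
  int i = bi, j = bj, state = 1, nmatch = 0;
  while (true) {
    unsigned char code = tb[(size_t)i * W + j];
    if (state == 1) {
      qc.push_back(i); sc2.push_back(j);
      if (q[i - 1] == s[j - 1]) ++nmatch;
      int mcode = code & 3;
      --i; --j;
      if (mcode == 0) break;
      state = mcode;
    } else if (state == 2) { // gap in subject
      qc.push_back(i); sc2.push_back(0);
      state = (code & 4) ? 2 : 1;
      --i;
    } else { // gap in query
      qc.push_back(0); sc2.push_back(j);
      state = (code & 8) ? 3 : 1;
      --j;
    }
  }
  std::reverse(qc.begin(), qc.end());
  std::reverse(sc2.begin(), sc2.end());
  return List::create(_["score"] = best,
                      _["qstart"] = i + 1, _["qend"] = bi,
                      _["sstart"] = j + 1, _["send"] = bj,
                      _["nmatch"] = nmatch,
                      _["length"] = (int)qc.size(),
                      _["qcols"] = wrap(qc), _["scols"] = wrap(sc2));
}
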