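#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps over integer-encoded
// amino-acid sequences.  Encoding: 0-based row/column index into the
// substitution matrix; the stop codon '*' is flagged separately (stopCode)
// and acts as a hard barrier: no local alignment may cross it, which is
// enforced by resetting all DP state at stop positions of the query frame.
//
// gapOpen/gapExtend are nonpositive; opening a gap of length 1 costs
// gapOpen + gapExtend (BLAST convention).

// Fast scan: best local score of q vs s (no coordinates).
static int sw_score(const int *q, int qlen, const int *s, int slen,
                    const int *sub, int ncol, int gapOpen, int gapExtend,
                    int stopCode, int *H, int *E) {
  int best = 0;
  const int NEG = -1000000;
  for (int j = 0; j <= slen; ++j) { H[j] = 0; E[j] = NEG; }
  for (int i = 1; i <= qlen; ++i) {
    int qi = q[i - 1];
    if (qi == stopCode) {          // barrier row: reset everything
      for (int j = 0; j <= slen; ++j) { H[j] = 0; E[j] = NEG; }
      continue;
    }
    const int *subrow = sub + (size_t)qi * ncol;
    int hdiag = 0;                 // H[i-1][j-1]
    int f = NEG;                   // horizontal gap state
    int hprev = 0;                 // H[i][j-1]
    for (int j = 1; j <= slen; ++j) {
      int e = std::max(E[j], H[j] + gapOpen) + gapExtend;
      f = std::max(f, hprev + gapOpen) + gapExtend;
      int h = hdiag + subrow[s[j - 1]];
      h = std::max(h, e);
      h = std::max(h, f);
      h = std::max(h, 0);
      hdiag = H[j];
      H[j] = h;
      E[j] = e;
      hprev = h;
      best = std::max(best, h);
    }
  }
  return best;
}

// [[Rcpp::export(name = ".swScanFrames")]]
IntegerMatrix swScanFrames(List frames, List db, IntegerMatrix submat,
                           int gapOpen, int gapExtend, int stopCode) {
  int nf = frames.size(), nd = db.size();
  int ncol = submat.ncol();
  std::vector<int> sub(submat.begin(), submat.end());
  // submat comes in column-major; we index row-major, so transpose once.
  std::vector<int> subrm((size_t)ncol * ncol);
  for (int r = 0; r < ncol; ++r)
    for (int c = 0; c < ncol; ++c)
      subrm[(size_t)r * ncol + c] = sub[(size_t)c * ncol + r];
  std::vector<std::vector<int>> fr(nf), dd(nd);
  for (int i = 0; i < nf; ++i) fr[i] = as<std::vector<int>>(frames[i]);
  for (int i = 0; i < nd; ++i) dd[i] = as<std::vector<int>>(db[i]);
  int maxs = 0;
  for (int d = 0; d < nd; ++d) maxs = std::max(maxs, (int)dd[d].size());
  std::vector<int> H(maxs + 1), E(maxs + 1);
  IntegerMatrix out(nd, 2);   // best score, best frame (1-based; ties -> lowest)
  for (int d = 0; d < nd; ++d) {
    int best = 0, bestf = 0;
    for (int f = 0; f < nf; ++f) {
      if (fr[f].empty() || dd[d].empty()) continue;
      int sc = sw_score(fr[f].data(), fr[f].size(), dd[d].data(), dd[d].size(),
                        subrm.data(), ncol, gapOpen, gapExtend, stopCode,
                        H.data(), E.data());
      if (sc > best) { best = sc; bestf = f + 1; }
    }
    out(d, 0) = best;
    out(d, 1) = bestf;
  }
  return out;
}

// Full DP with traceback; returns score, 0-based half-open query/subject
// spans of the best local alignment and alignment statistics.
// Tie-break: among equal-scoring cells the first reached in row-major
// scan order (smallest query end, then subject end) is kept.
// [[Rcpp::export(name = ".swTraceback")]]
List swTraceback(IntegerVector qv, IntegerVector sv, IntegerMatrix submat,
                 int gapOpen, int gapExtend, int stopCode) {
  int qlen = qv.size(), slen = sv.size();
  int ncol = submat.ncol();
  const int NEG = -1000000;
  std::vector<int> q = as<std::vector<int>>(qv), s = as<std::vector<int>>(sv);
  size_t ncell = (size_t)(qlen + 1) * (slen + 1);
  std::vector<int> H(ncell, 0), E(ncell, NEG), F(ncell, NEG);
  // trace codes: 0 stop, 1 diag, 2 up (gap in subject), 3 left (gap in query)
  std::vector<unsigned char> TH(ncell, 0), TE(ncell, 0), TF(ncell, 0);
  int best = 0; size_t bestCell = 0;
  for (int i = 1; i <= qlen; ++i) {
    int qi = q[i - 1];
    size_t row = (size_t)i * (slen + 1), prow = row - (slen + 1);
    if (qi == stopCode) continue;  // row stays H=0, E=F=-inf: barrier
    for (int j = 1; j <= slen; ++j) {
      // E: gap in query consumes subject residue (move left->right)
      int Eext = E[row + j - 1] + gapExtend;
      int Eopen = H[row + j - 1] + gapOpen + gapExtend;
      if (Eopen >= Eext) { E[row + j] = Eopen; TE[row + j] = 0; }
      else { E[row + j] = Eext; TE[row + j] = 1; }
      // F: gap in subject consumes query residues; a stop row keeps
      // F = -inf so no gap can bridge across it
      int Fext = F[prow + j] + gapExtend;
      int Fopen = H[prow + j] + gapOpen + gapExtend;
      if (Fopen >= Fext) { F[row + j] = Fopen; TF[row + j] = 0; }
      else { F[row + j] = Fext; TF[row + j] = 1; }
      int diag = H[prow + j - 1] + submat(qi, s[j - 1]);
      int h = 0; unsigned char th = 0;
      if (diag > h) { h = diag; th = 1; }
      if (F[row + j] > h) { h = F[row + j]; th = 2; }
      if (E[row + j] > h) { h = E[row + j]; th = 3; }
      H[row + j] = h; TH[row + j] = th;
      if (h > best) { best = h; bestCell = row + j; }
    }
  }
  int qend = 0, send = 0, qstart = 0, sstart = 0;
  int matches = 0, mism = 0, alnLen = 0, gapOpens = 0;
  if (best > 0) {
    int i = (int)(bestCell / (slen + 1)), j = (int)(bestCell % (slen + 1));
    qend = i; send = j;
    int state = 0;  // 0 = in H
    while (i > 0 && j > 0) {
      size_t cell = (size_t)i * (slen + 1) + j;
      if (state == 0) {
        unsigned char th = TH[cell];
        if (th == 0) break;
        if (th == 1) {
          ++alnLen;
          if (q[i - 1] == s[j - 1]) ++matches; else ++mism;
          --i; --j;
        } else if (th == 2) state = 2; else state = 3;
      } else if (state == 2) {  // F: gap in subject
        ++alnLen;
        if (TF[cell] == 0) { ++gapOpens; state = 0; }
        --i;
      } else {                  // E: gap in query
        ++alnLen;
        if (TE[cell] == 0) { ++gapOpens; state = 0; }
        --j;
      }
    }
    qstart = i; sstart = j;
  }
  return List::create(_["score"] = best,
                      _["qstart"] = qstart, _["qend"] = qend,
                      _["sstart"] = sstart, _["send"] = send,
                      _["matches"] = matches, _["mismatches"] = mism,
                      _["alnLen"] = alnLen, _["gapOpens"] = gapOpens);
}
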