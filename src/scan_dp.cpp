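// Smith-Waterman-style local alignment of a position-specific log-odds
// profile against a sequence, with affine gaps.  Non-overlapping hits above
// a score threshold are recovered by iterative masking of reported regions.
//
// Sequence codes: 0=A 1=C 2=G 3=T 4=N (scores 0, background) 5=masked.
// States: M consumes (base, column); Ix consumes a base (insertion relative
// to the profile); Iy consumes a column (deletion).  All cross transitions
// between Ix and Iy are allowed.  Local alignments start and end in M.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG = -1e30;

// [[Rcpp::export]]
List scan_dp_cpp(NumericMatrix logodds, IntegerVector seq_codes,
                 double gap_open, double gap_extend, double threshold,
                 int max_hits = 1000) {
  const int L = logodds.ncol();   // profile columns; logodds is 4 x L
  const int N = seq_codes.size();
  std::vector<int> seq(seq_codes.begin(), seq_codes.end());
  std::vector<int> hit_start, hit_end;
  std::vector<double> hit_score;

  if (N == 0 || L == 0)
    return List::create(_["start"] = IntegerVector(0),
                        _["end"] = IntegerVector(0),
                        _["score"] = NumericVector(0));

  std::vector<double> M((N + 1) * (L + 1), NEG), Ix(M), Iy(M);
  // traceback: for M cells 0=fresh 1=M 2=Ix 3=Iy; for Ix/Iy 1=M 2=Ix 3=Iy
  std::vector<unsigned char> pM((N + 1) * (L + 1), 0), pIx(pM), pIy(pM);
  const int W = L + 1;

  for (int iter = 0; iter < max_hits; ++iter) {
    std::fill(M.begin(), M.end(), NEG);
    std::fill(Ix.begin(), Ix.end(), NEG);
    std::fill(Iy.begin(), Iy.end(), NEG);
    double best = NEG;
    int bi = -1, bj = -1;
    for (int i = 1; i <= N; ++i) {
      const int c = seq[i - 1];
      for (int j = 1; j <= L; ++j) {
        const int id = i * W + j, dg = (i - 1) * W + (j - 1);
        // match / mismatch
        double s;
        if (c <= 3) s = logodds(c, j - 1);
        else if (c == 4) s = 0.0;          // N scores as background
        else s = NEG;                      // masked
        double mbest = 0.0; unsigned char mp = 0;
        if (M[dg] > mbest) { mbest = M[dg]; mp = 1; }
        if (Ix[dg] > mbest) { mbest = Ix[dg]; mp = 2; }
        if (Iy[dg] > mbest) { mbest = Iy[dg]; mp = 3; }
        M[id] = mbest + s; pM[id] = mp;
        // Ix: consume a base, stay on column j
        const int up = (i - 1) * W + j;
        double xo = M[up] + gap_open, xe = Ix[up] + gap_extend,
               xy = Iy[up] + gap_open;
        if (xo >= xe && xo >= xy) { Ix[id] = xo; pIx[id] = 1; }
        else if (xe >= xy)        { Ix[id] = xe; pIx[id] = 2; }
        else                      { Ix[id] = xy; pIx[id] = 3; }
        // Iy: consume a column, stay on base i
        const int lf = i * W + (j - 1);
        double yo = M[lf] + gap_open, ye = Iy[lf] + gap_extend,
               yx = Ix[lf] + gap_open;
        if (yo >= ye && yo >= yx) { Iy[id] = yo; pIy[id] = 1; }
        else if (ye >= yx)        { Iy[id] = ye; pIy[id] = 2; }
        else                      { Iy[id] = yx; pIy[id] = 3; }
        if (M[id] > best) { best = M[id]; bi = i; bj = j; }
      }
    }
    if (best < threshold || bi < 0) break;
    // traceback from (bi, bj) in state M to the fresh start
    int i = bi, j = bj, state = 0;    // 0=M 1=Ix 2=Iy
    int start_i = bi;
    for (;;) {
      if (state == 0) {
        unsigned char p = pM[i * W + j];
        if (p == 0) { start_i = i - 1; break; }
        state = (p == 1) ? 0 : (p == 2 ? 1 : 2);
        --i; --j;
      } else if (state == 1) {
        unsigned char p = pIx[i * W + j];
        state = (p == 1) ? 0 : (p == 2 ? 1 : 2);
        --i;
      } else {
        unsigned char p = pIy[i * W + j];
        state = (p == 1) ? 0 : (p == 2 ? 1 : 2);
        --j;
      }
    }
    hit_start.push_back(start_i);
    hit_end.push_back(bi);
    hit_score.push_back(best);
    for (int k = start_i; k < bi; ++k) seq[k] = 5;   // mask and rescan
  }
  return List::create(_["start"] = wrap(hit_start),
                      _["end"] = wrap(hit_end),
                      _["score"] = wrap(hit_score));
}
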