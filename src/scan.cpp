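#include <Rcpp.h>
using namespace Rcpp;

// Sequence codes: 1..4 = A,C,G,T; anything else (N) scores 0 (background).

static inline double colscore(const NumericMatrix& mat, int code, int j) {
  return (code >= 1 && code <= 4) ? mat(code - 1, j) : 0.0;
}

// Score of the full PWM at every start position of one sequence.
// [[Rcpp::export]]
NumericVector pwm_scores_cpp(IntegerVector codes, NumericMatrix mat) {
  const int n = codes.size(), w = mat.ncol();
  const int np = n - w + 1;
  if (np < 1) return NumericVector(0);
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double s = 0.0;
    for (int j = 0; j < w; ++j) s += colscore(mat, codes[p + j], j);
    out[p] = s;
  }
  return out;
}

// Best match score of every contiguous column sub-range [a,b] of a PWM in
// each sequence, over both strands. fmat is the 4 x w forward log-odds
// matrix and rmat its reverse complement (rows A<->T, C<->G swapped and
// columns reversed); a sub-range [a,b] on the minus strand is the
// [w-b+1, w-a+1] sub-range of rmat. Alignments must lie fully inside the
// sequence. Returns an n_seq x (w*w) matrix, column index (a-1)*w + b
// (1-based a <= b); unused cells are -Inf.
// [[Rcpp::export]]
NumericMatrix best_subrange_scores_cpp(List codes_list, NumericMatrix fmat,
                                       NumericMatrix rmat) {
  const int w = fmat.ncol();
  const int ns = codes_list.size();
  NumericMatrix out(ns, w * w);
  std::fill(out.begin(), out.end(), R_NegInf);
  std::vector<double> run;
  for (int s = 0; s < ns; ++s) {
    IntegerVector codes = codes_list[s];
    const int n = codes.size();
    for (int strand = 0; strand < 2; ++strand) {
      const NumericMatrix& mat = strand == 0 ? fmat : rmat;
      for (int a = 0; a < w; ++a) {
        // run[p] accumulates the score of columns a..b starting at p
        int len = n; // alignments available for width (b - a + 1)
        run.assign(n, 0.0);
        for (int b = a; b < w; ++b) {
          len = n - (b - a + 1) + 1;
          if (len < 1) break;
          double best = R_NegInf;
          for (int p = 0; p < len; ++p) {
            run[p] += colscore(mat, codes[p + b - a], b);
            if (run[p] > best) best = run[p];
          }
          // map strand sub-range back to forward column coordinates
          int af = strand == 0 ? a : w - 1 - b;
          int bf = strand == 0 ? b : w - 1 - a;
          int idx = af * w + bf;
          if (best > out(s, idx)) out(s, idx) = best;
        }
      }
    }
  }
  return out;
}
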