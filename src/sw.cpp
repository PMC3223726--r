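// Smith-Waterman local alignment with affine gaps (Gotoh algorithm).
//
// Gap convention: a gap of length k costs gap_open + k * gap_ext (the
// first gapped residue pays both the opening and the extension penalty).
// Scores below 0 are clamped to 0 (local alignment); an all-negative
// scoring space therefore yields score 0 = the empty alignment.
//
// Sequences arrive as 0-based integer vectors indexing rows/columns of
// the substitution matrix.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static double sw_score_only(const int* a, int na, const int* b, int nb,
                            const NumericMatrix& S, double go, double ge) {
  const double NEG = -1e30;
  std::vector<double> H(nb + 1, 0.0), E(nb + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= na; ++i) {
    double Hdiag = 0.0;   // H[i-1][j-1]
    double F = NEG;       // gap in B (vertical), recomputed per row
    H[0] = 0.0;
    for (int j = 1; j <= nb; ++j) {
      E[j] = std::max(E[j] - ge, H[j] - go - ge);        // H[i-1][j]
      F = std::max(F - ge, H[j - 1] - go - ge);          // H[i][j-1] (current row)
      double match = Hdiag + S(a[i - 1], b[j - 1]);
      Hdiag = H[j];
      double h = match;
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0.0) h = 0.0;
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_matrix_cpp")]]
NumericMatrix sw_score_matrix_cpp(List a, List b, NumericMatrix S,
                                  double gap_open, double gap_ext) {
  int na = a.size(), nb = b.size();
  NumericMatrix out(na, nb);
  std::vector<std::vector<int> > av(na), bv(nb);
  for (int i = 0; i < na; ++i)
    av[i] = as<std::vector<int> >(a[i]);
  for (int j = 0; j < nb; ++j)
    bv[j] = as<std::vector<int> >(b[j]);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j)
      out(i, j) = sw_score_only(av[i].data(), (int)av[i].size(),
                                bv[j].data(), (int)bv[j].size(),
                                S, gap_open, gap_ext);
  return out;
}

// Full DP with traceback; returns (score, matches, aligned_columns).
// Aligned columns count every column of the local alignment, gap columns
// included. The empty alignment reports 0 matches over 0 columns.
// [[Rcpp::export(name = ".sw_align_stats_cpp")]]
NumericVector sw_align_stats_cpp(IntegerVector a, IntegerVector b,
                                 NumericMatrix S, double gap_open,
                                 double gap_ext) {
  int na = a.size(), nb = b.size();
  const double NEG = -1e30;
  // state matrices: H (match/mismatch end), E (gap in a / consume b),
  // F (gap in b / consume a); traceback codes per cell
  std::vector<std::vector<double> > H(na + 1, std::vector<double>(nb + 1, 0.0));
  std::vector<std::vector<double> > E(na + 1, std::vector<double>(nb + 1, NEG));
  std::vector<std::vector<double> > F(na + 1, std::vector<double>(nb + 1, NEG));
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      E[i][j] = std::max(E[i][j - 1] - gap_ext,
                         H[i][j - 1] - gap_open - gap_ext);
      F[i][j] = std::max(F[i - 1][j] - gap_ext,
                         H[i - 1][j] - gap_open - gap_ext);
      double h = H[i - 1][j - 1] + S(a[i - 1], b[j - 1]);
      if (E[i][j] > h) h = E[i][j];
      if (F[i][j] > h) h = F[i][j];
      if (h < 0.0) h = 0.0;
      H[i][j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int matches = 0, columns = 0;
  if (best > 0.0) {
    int i = bi, j = bj;
    char state = 'H';
    while (i > 0 && j > 0) {
      if (state == 'H') {
        if (H[i][j] == 0.0) break;
        if (H[i][j] == E[i][j]) { state = 'E'; continue; }
        if (H[i][j] == F[i][j]) { state = 'F'; continue; }
        // diagonal
        ++columns;
        if (a[i - 1] == b[j - 1]) ++matches;
        --i; --j;
      } else if (state == 'E') {
        ++columns;                       // gap column (gap in a)
        bool opened = (E[i][j] == H[i][j - 1] - gap_open - gap_ext);
        --j;
        if (opened) state = 'H';
      } else {                           // state == 'F'
        ++columns;                       // gap column (gap in b)
        bool opened = (F[i][j] == H[i - 1][j] - gap_open - gap_ext);
        --i;
        if (opened) state = 'H';
      }
    }
  }
  return NumericVector::create(best, (double)matches, (double)columns);
}
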