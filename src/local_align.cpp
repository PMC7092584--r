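#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap Smith-Waterman with traceback.
// Sequences are encoded 0..4 = A,C,G,T,N; `smat` is the 5x5 pair-score
// matrix in (a, b) space. Gap of length L costs open + (L-1)*extend
// (both passed as non-negative costs). Ties resolve to the smallest
// (end_i, end_j) cell, i.e. leftmost-in-a then leftmost-in-b, and the
// traceback prefers diagonal over gap-in-b over gap-in-a so the optimum
// path is deterministic.
// Returns 1-based inclusive aligned regions, the match count and the
// number of alignment columns (gap columns included).

static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string a, std::string b, NumericMatrix smat,
              double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<int> ea(n), eb(m);
  for (int i = 0; i < n; ++i) ea[i] = enc(a[i]);
  for (int j = 0; j < m; ++j) eb[j] = enc(b[j]);

  // H: best ending at (i,j) with a[i] aligned to b[j] or gap states
  // E: gap in a (consumes b), F: gap in b (consumes a)
  const double NEG = -1e30;
  std::vector<std::vector<double>> H(n + 1, std::vector<double>(m + 1, 0.0));
  std::vector<std::vector<double>> E(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> F(n + 1, std::vector<double>(m + 1, NEG));
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E[i][j] = std::max(H[i][j - 1] - gap_open, E[i][j - 1] - gap_extend);
      F[i][j] = std::max(H[i - 1][j] - gap_open, F[i - 1][j] - gap_extend);
      double diag = H[i - 1][j - 1] + smat(ea[i - 1], eb[j - 1]);
      double h = std::max(0.0, std::max(diag, std::max(E[i][j], F[i][j])));
      H[i][j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["a_start"] = NA_INTEGER,
                        _["a_end"] = NA_INTEGER, _["b_start"] = NA_INTEGER,
                        _["b_end"] = NA_INTEGER, _["matches"] = 0,
                        _["aligned_cols"] = 0, _["a_aligned"] = 0,
                        _["b_aligned"] = 0);
  }
  // traceback from (bi, bj), state M
  int i = bi, j = bj;
  int matches = 0, cols = 0, a_aln = 0, b_aln = 0;
  int state = 0; // 0 = H, 1 = E (gap in a), 2 = F (gap in b)
  const double eps = 1e-9;
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (H[i][j] <= eps) break;
      double diag = H[i - 1][j - 1] + smat(ea[i - 1], eb[j - 1]);
      if (std::abs(H[i][j] - diag) < eps) {
        if (ea[i - 1] == eb[j - 1] && ea[i - 1] != 4) ++matches;
        ++cols; ++a_aln; ++b_aln; --i; --j;
      } else if (std::abs(H[i][j] - F[i][j]) < eps) {
        state = 2;
      } else if (std::abs(H[i][j] - E[i][j]) < eps) {
        state = 1;
      } else {
        break; // H == 0 restart
      }
    } else if (state == 1) { // gap in a: consume b[j]
      ++cols; ++b_aln;
      if (std::abs(E[i][j] - (H[i][j - 1] - gap_open)) < eps) state = 0;
      --j;
    } else { // gap in b: consume a[i]
      ++cols; ++a_aln;
      if (std::abs(F[i][j] - (H[i - 1][j] - gap_open)) < eps) state = 0;
      --i;
    }
  }
  return List::create(_["score"] = best,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj,
                      _["matches"] = matches, _["aligned_cols"] = cols,
                      _["a_aligned"] = a_aln, _["b_aligned"] = b_aln);
}
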