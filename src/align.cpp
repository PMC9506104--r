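#include <Rcpp.h>
using namespace Rcpp;

// Affine gap convention (NCBI-style): a gap of length k costs
// gap_open + k * gap_extend, i.e. opening a 1-residue gap costs
// gap_open + gap_extend.

// Score-only Smith-Waterman (Gotoh), linear memory in the subject.
// q, s: 0-based integer encodings into `sub`.
// [[Rcpp::export]]
int sw_score_cpp(const IntegerVector& q, const IntegerVector& s,
                 const IntegerMatrix& sub, int gap_open, int gap_extend) {
  const int m = q.size(), n = s.size();
  std::vector<int> H(n + 1, 0), E(n + 1, INT_MIN / 4);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int Hdiag = 0;      // H[i-1][j-1]
    int F = INT_MIN / 4; // gap in subject, running along row
    for (int j = 1; j <= n; ++j) {
      E[j] = std::max(H[j] - gap_open - gap_extend, E[j] - gap_extend);
      F    = std::max(H[j - 1] - gap_open - gap_extend, F - gap_extend);
      int h = Hdiag + sub(q[i - 1], s[j - 1]);
      h = std::max(h, E[j]);
      h = std::max(h, F);
      h = std::max(h, 0);
      Hdiag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Full Smith-Waterman with traceback. Returns the optimal local alignment;
// among co-optimal cells the one with smallest (i, j) is used, and the
// traceback prefers diagonal, then gap-in-subject, then gap-in-query.
// [[Rcpp::export]]
List sw_align_cpp(const IntegerVector& q, const IntegerVector& s,
                  const IntegerMatrix& sub, int gap_open, int gap_extend) {
  const int m = q.size(), n = s.size();
  const int NEG = INT_MIN / 4;
  IntegerMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  for (int j = 0; j <= n; ++j) { H(0, j) = 0; E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= m; ++i) { H(i, 0) = 0; E(i, 0) = NEG; F(i, 0) = NEG; }

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E(i, j) = std::max(H(i, j - 1) - gap_open - gap_extend,
                         E(i, j - 1) - gap_extend);
      F(i, j) = std::max(H(i - 1, j) - gap_open - gap_extend,
                         F(i - 1, j) - gap_extend);
      int h = H(i - 1, j - 1) + sub(q[i - 1], s[j - 1]);
      h = std::max(h, E(i, j));
      h = std::max(h, F(i, j));
      h = std::max(h, 0);
      H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best == 0)
    return List::create(_["score"] = 0);

  // traceback from (bi, bj) until H == 0
  std::vector<int> ops; // 0 = diag, 1 = gap in subject (consume q), 2 = gap in query
  int i = bi, j = bj;
  int state = 0; // 0 in H, 1 in E, 2 in F
  while (!(state == 0 && H(i, j) == 0)) {
    if (state == 0) {
      if (i > 0 && j > 0 &&
          H(i, j) == H(i - 1, j - 1) + sub(q[i - 1], s[j - 1])) {
        ops.push_back(0); --i; --j;
      } else if (H(i, j) == F(i, j)) {
        state = 2;
      } else if (H(i, j) == E(i, j)) {
        state = 1;
      } else break; // H == 0 handled by loop condition
    } else if (state == 1) { // E: gap in query, consume subject
      ops.push_back(2);
      if (E(i, j) == E(i, j - 1) - gap_extend) { --j; }
      else { --j; state = 0; }
    } else { // F: gap in subject, consume query
      ops.push_back(1);
      if (F(i, j) == F(i - 1, j) - gap_extend) { --i; }
      else { --i; state = 0; }
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best,
                      _["ops"] = wrap(ops),
                      _["q_start"] = i, _["q_end"] = bi,   // 0-based half-open
                      _["s_start"] = j, _["s_end"] = bj);
}

// Global (Needleman-Wunsch/Gotoh) alignment of two profiles given the
// precomputed column-pair score matrix `cost` (nrow = profile A columns,
// ncol = profile B columns). Terminal gaps are penalized. Returns the edit
// path as integer ops: 0 = match columns, 1 = gap in B, 2 = gap in A.
// [[Rcpp::export]]
IntegerVector profile_nw_cpp(const NumericMatrix& cost,
                             double gap_open, double gap_extend) {
  const int m = cost.nrow(), n = cost.ncol();
  const double NEG = -1e18;
  NumericMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  H(0, 0) = 0; E(0, 0) = NEG; F(0, 0) = NEG;
  for (int j = 1; j <= n; ++j) {
    E(0, j) = -gap_open - j * gap_extend;
    H(0, j) = E(0, j); F(0, j) = NEG;
  }
  for (int i = 1; i <= m; ++i) {
    F(i, 0) = -gap_open - i * gap_extend;
    H(i, 0) = F(i, 0); E(i, 0) = NEG;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E(i, j) = std::max(H(i, j - 1) - gap_open - gap_extend,
                         E(i, j - 1) - gap_extend);
      F(i, j) = std::max(H(i - 1, j) - gap_open - gap_extend,
                         F(i - 1, j) - gap_extend);
      double h = H(i - 1, j - 1) + cost(i - 1, j - 1);
      h = std::max(h, E(i, j));
      h = std::max(h, F(i, j));
      H(i, j) = h;
    }
  }
  std::vector<int> ops;
  int i = m, j = n, state = 0;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i > 0 && j > 0 &&
          std::abs(H(i, j) - (H(i - 1, j - 1) + cost(i - 1, j - 1))) < eps) {
        ops.push_back(0); --i; --j;
      } else if (i > 0 && std::abs(H(i, j) - F(i, j)) < eps) {
        state = 2;
      } else if (j > 0 && std::abs(H(i, j) - E(i, j)) < eps) {
        state = 1;
      } else if (i == 0) { ops.push_back(2); --j; }
      else { ops.push_back(1); --i; }
    } else if (state == 1) {
      ops.push_back(2);
      if (j > 1 && std::abs(E(i, j) - (E(i, j - 1) - gap_extend)) < eps) { --j; }
      else { --j; state = 0; }
    } else {
      ops.push_back(1);
      if (i > 1 && std::abs(F(i, j) - (F(i - 1, j) - gap_extend)) < eps) { --i; }
      else { --i; state = 0; }
    }
  }
  std::reverse(ops.begin(), ops.end());
  return wrap(ops);
}
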