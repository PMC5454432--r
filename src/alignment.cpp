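#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap conventions follow BLAST: a gap of length k costs
// open + k * extend, so the first gapped residue costs open + extend.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
double sw_score_c(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG_INF);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diag = 0.0;       // H[i-1][j-1]
    double F = NEG_INF;      // gap in b (vertical) for current row
    double Hprev = 0.0;      // H[i][j-1]
    E[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      F = std::max(H[j] - (gap_open + gap_extend), F - gap_extend);
      E[j] = std::max(Hprev - (gap_open + gap_extend), E[j] - gap_extend);
      double h = diag + S(a[i - 1], b[j - 1]);
      h = std::max(h, E[j]);
      h = std::max(h, F);
      h = std::max(h, 0.0);
      diag = H[j];
      H[j] = h;
      Hprev = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// All-vs-all Smith-Waterman scores; diagonal holds self-alignment scores.
// [[Rcpp::export]]
NumericMatrix sw_allpairs_c(List seqs, NumericMatrix S,
                            double gap_open, double gap_extend) {
  int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<IntegerVector> v(n);
  for (int i = 0; i < n; ++i) v[i] = as<IntegerVector>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double s = sw_score_c(v[i], v[j], S, gap_open, gap_extend);
      out(i, j) = s;
      out(j, i) = s;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Scores of one query against many targets.
// [[Rcpp::export]]
NumericVector sw_many_c(IntegerVector query, List targets, NumericMatrix S,
                        double gap_open, double gap_extend) {
  int n = targets.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = sw_score_c(query, as<IntegerVector>(targets[i]), S,
                        gap_open, gap_extend);
  return out;
}

// Global (Needleman-Wunsch) alignment of two residue-frequency profiles.
// profA, profB: alphabet x length frequency matrices (columns sum to <= 1;
// gap mass simply contributes no score). Returns a vector of moves read
// left to right: 1 = column from both, 2 = gap in A (B advances),
// 3 = gap in B (A advances).
// [[Rcpp::export]]
IntegerVector nw_profile_c(NumericMatrix profA, NumericMatrix profB,
                           NumericMatrix S, double gap_open,
                           double gap_extend) {
  int n = profA.ncol(), m = profB.ncol(), K = S.nrow();
  if (profA.nrow() != K || profB.nrow() != K)
    stop("profile alphabet does not match substitution matrix");

  // expected column-vs-column score
  NumericMatrix cs(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int a = 0; a < K; ++a) {
        double fa = profA(a, i);
        if (fa == 0.0) continue;
        for (int b = 0; b < K; ++b) {
          double fb = profB(b, j);
          if (fb != 0.0) s += fa * fb * S(a, b);
        }
      }
      cs(i, j) = s;
    }

  std::vector<double> H((n + 1) * (m + 1)), E((n + 1) * (m + 1)),
      F((n + 1) * (m + 1));
  std::vector<signed char> tb((n + 1) * (m + 1));  // 1 diag, 2 left, 3 up
  int W = m + 1;
  H[0] = 0.0; E[0] = F[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    E[j] = -(gap_open + gap_extend * j);
    H[j] = E[j];
    F[j] = NEG_INF;
    tb[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    F[i * W] = -(gap_open + gap_extend * i);
    H[i * W] = F[i * W];
    E[i * W] = NEG_INF;
    tb[i * W] = 3;
    for (int j = 1; j <= m; ++j) {
      double e = std::max(H[i * W + j - 1] - (gap_open + gap_extend),
                          E[i * W + j - 1] - gap_extend);
      double f = std::max(H[(i - 1) * W + j] - (gap_open + gap_extend),
                          F[(i - 1) * W + j] - gap_extend);
      double d = H[(i - 1) * W + j - 1] + cs(i - 1, j - 1);
      E[i * W + j] = e;
      F[i * W + j] = f;
      double h = d;
      signed char t = 1;
      if (e > h) { h = e; t = 2; }
      if (f > h) { h = f; t = 3; }
      H[i * W + j] = h;
      tb[i * W + j] = t;
    }
  }
  std::vector<int> moves;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    signed char t = tb[i * W + j];
    if (t == 1) { moves.push_back(1); --i; --j; }
    else if (t == 2) { moves.push_back(2); --j; }
    else { moves.push_back(3); --i; }
  }
  std::reverse(moves.begin(), moves.end());
  return wrap(moves);
}

// Ungapped identities of a spacer against every window of a genome strand.
// Sequences are integer-coded; codes >= 4 (ambiguous/N) never match.
// Returns an integer vector of match counts, one per window start.
// [[Rcpp::export]]
IntegerVector window_counts_c(IntegerVector spacer, IntegerVector genome) {
  int L = spacer.size(), G = genome.size();
  if (L > G) return IntegerVector(0);
  int W = G - L + 1;
  IntegerVector out(W);
  for (int w = 0; w < W; ++w) {
    int c = 0;
    for (int k = 0; k < L; ++k) {
      int s = spacer[k];
      if (s < 4 && s == genome[w + k]) ++c;
    }
    out[w] = c;
  }
  return out;
}
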