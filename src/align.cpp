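#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment over a precomputed column-pair
// score matrix S (rows = positions of a, cols = positions of b), with affine
// gap cost open + k*ext for a gap of length k. End gaps are penalized.
// Traceback ties resolve in fixed order (diagonal, gap-in-b, gap-in-a) so the
// alignment is deterministic.
// [[Rcpp::export]]
List gotoh_align_cpp(NumericMatrix S, double gap_open, double gap_ext) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);

  M(0, 0) = 0.0; Ix(0, 0) = NEG; Iy(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Iy(i, 0) = NEG;
    Ix(i, 0) = -(gap_open + i * gap_ext);
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; Ix(0, j) = NEG;
    Iy(0, j) = -(gap_open + j * gap_ext);
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = std::max(M(i - 1, j - 1), std::max(Ix(i - 1, j - 1), Iy(i - 1, j - 1)));
      M(i, j) = d + S(i - 1, j - 1);
      Ix(i, j) = std::max(std::max(M(i - 1, j) - gap_open - gap_ext,
                                   Ix(i - 1, j) - gap_ext),
                          Iy(i - 1, j) - gap_open - gap_ext);
      Iy(i, j) = std::max(std::max(M(i, j - 1) - gap_open - gap_ext,
                                   Iy(i, j - 1) - gap_ext),
                          Ix(i, j - 1) - gap_open - gap_ext);
    }
  }

  double score = std::max(M(n, m), std::max(Ix(n, m), Iy(n, m)));

  // traceback: state 0 = M, 1 = Ix (consumes a, gap in b), 2 = Iy
  std::vector<int> ai, bi;
  int i = n, j = m;
  int state = (M(n, m) >= Ix(n, m) && M(n, m) >= Iy(n, m)) ? 0 :
              (Ix(n, m) >= Iy(n, m) ? 1 : 2);
  while (i > 0 || j > 0) {
    if (i == 0) { ai.push_back(0); bi.push_back(j); --j; continue; }
    if (j == 0) { ai.push_back(i); bi.push_back(0); --i; continue; }
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      double target = M(i, j) - S(i - 1, j - 1);
      if (M(i - 1, j - 1) >= target) state = 0;
      else if (Ix(i - 1, j - 1) >= target) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      ai.push_back(i); bi.push_back(0);
      double cur = Ix(i, j);
      if (M(i - 1, j) - gap_open - gap_ext >= cur) state = 0;
      else if (Ix(i - 1, j) - gap_ext >= cur) state = 1;
      else state = 2;
      --i;
    } else {
      ai.push_back(0); bi.push_back(j);
      double cur = Iy(i, j);
      if (M(i, j - 1) - gap_open - gap_ext >= cur) state = 0;
      else if (Iy(i, j - 1) - gap_ext >= cur) state = 2;
      else state = 1;
      --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = score,
                      _["ai"] = IntegerVector(ai.begin(), ai.end()),
                      _["bi"] = IntegerVector(bi.begin(), bi.end()));
}

// Mean pairwise substitution score between every column of profile A and
// every column of profile B. Profiles are integer-coded (1-based index into
// subm; 0 = gap). Residue-gap pairs score gap_pair; gap-gap pairs score 0.
// [[Rcpp::export]]
NumericMatrix profile_score_cpp(IntegerMatrix A, IntegerMatrix B,
                                NumericMatrix subm, double gap_pair) {
  const int r1 = A.nrow(), L1 = A.ncol();
  const int r2 = B.nrow(), L2 = B.ncol();
  NumericMatrix S(L1, L2);
  const double denom = (double)r1 * (double)r2;
  for (int i = 0; i < L1; ++i) {
    for (int j = 0; j < L2; ++j) {
      double s = 0.0;
      for (int a = 0; a < r1; ++a) {
        int ca = A(a, i);
        for (int b = 0; b < r2; ++b) {
          int cb = B(b, j);
          if (ca == 0 && cb == 0) continue;
          else if (ca == 0 || cb == 0) s += gap_pair;
          else s += subm(ca - 1, cb - 1);
        }
      }
      S(i, j) = s / denom;
    }
  }
  return S;
}

// Score and identical-pair count of the optimal global alignment of two
// integer-encoded sequences (1-based codes into subm). Same recursion and
// tie order as gotoh_align_cpp, but with flat buffers and no string
// handling: this is the hot path of greedy identity clustering.
// [[Rcpp::export]]
List align_identity_cpp(IntegerVector ia, IntegerVector ib,
                        NumericMatrix subm, double gap_open, double gap_ext) {
  const int n = ia.size(), m = ib.size();
  const double NEG = -1e30;
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), Ix((n + 1) * W, NEG),
      Iy((n + 1) * W, NEG);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) Ix[i * W] = -(gap_open + i * gap_ext);
  for (int j = 1; j <= m; ++j) Iy[j] = -(gap_open + j * gap_ext);
  const double* sm = subm.begin();
  const int nr = subm.nrow();
  for (int i = 1; i <= n; ++i) {
    const int ci = ia[i - 1] - 1;
    double* Mi = &M[i * W]; double* Mp = &M[(i - 1) * W];
    double* Ixi = &Ix[i * W]; double* Ixp = &Ix[(i - 1) * W];
    double* Iyi = &Iy[i * W]; double* Iyp = &Iy[(i - 1) * W];
    for (int j = 1; j <= m; ++j) {
      const int cj = ib[j - 1] - 1;
      double d = std::max(Mp[j - 1], std::max(Ixp[j - 1], Iyp[j - 1]));
      Mi[j] = d + sm[ci + nr * cj];
      Ixi[j] = std::max(std::max(Mp[j] - gap_open - gap_ext,
                                 Ixp[j] - gap_ext),
                        Iyp[j] - gap_open - gap_ext);
      Iyi[j] = std::max(std::max(Mi[j - 1] - gap_open - gap_ext,
                                 Iyi[j - 1] - gap_ext),
                        Ixi[j - 1] - gap_open - gap_ext);
    }
  }
  double score = std::max(M[n * W + m], std::max(Ix[n * W + m], Iy[n * W + m]));
  // traceback counting identical aligned pairs
  int i = n, j = m, ident = 0;
  int state = (M[n * W + m] >= Ix[n * W + m] && M[n * W + m] >= Iy[n * W + m])
                  ? 0 : (Ix[n * W + m] >= Iy[n * W + m] ? 1 : 2);
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (ia[i - 1] == ib[j - 1]) ++ident;
      double target = M[i * W + j] - sm[(ia[i - 1] - 1) + nr * (ib[j - 1] - 1)];
      if (M[(i - 1) * W + j - 1] >= target) state = 0;
      else if (Ix[(i - 1) * W + j - 1] >= target) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      double cur = Ix[i * W + j];
      if (M[(i - 1) * W + j] - gap_open - gap_ext >= cur) state = 0;
      else if (Ix[(i - 1) * W + j] - gap_ext >= cur) state = 1;
      else state = 2;
      --i;
    } else {
      double cur = Iy[i * W + j];
      if (M[i * W + j - 1] - gap_open - gap_ext >= cur) state = 0;
      else if (Iy[i * W + j - 1] - gap_ext >= cur) state = 2;
      else state = 1;
      --j;
    }
  }
  return List::create(_["score"] = score, _["n_identical"] = ident);
}
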