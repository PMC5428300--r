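#include <Rcpp.h>
#include <string>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment with affine gap penalties (Gotoh).
// A gap of length g costs gap_open + g * gap_extend (both <= 0).
// 'N' never scores as a match. Traceback ties resolved deterministically
// with preference M (substitution) > X (gap in b) > Y (gap in a).
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  // matrices stored row-major, (n+1) x (m+1)
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG); // a consumed, gap in b
  std::vector<double> Y((n + 1) * (m + 1), NEG); // b consumed, gap in a
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = gap_open + i * gap_extend;
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = gap_open + j * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? match : mismatch;
      double prev = std::max(M[at(i - 1, j - 1)],
                    std::max(X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)]));
      M[at(i, j)] = prev + s;
      X[at(i, j)] = std::max(M[at(i - 1, j)] + gap_open + gap_extend,
                    std::max(X[at(i - 1, j)] + gap_extend,
                             Y[at(i - 1, j)] + gap_open + gap_extend));
      Y[at(i, j)] = std::max(M[at(i, j - 1)] + gap_open + gap_extend,
                    std::max(Y[at(i, j - 1)] + gap_extend,
                             X[at(i, j - 1)] + gap_open + gap_extend));
    }
  }

  double best = std::max(M[at(n, m)], std::max(X[at(n, m)], Y[at(n, m)]));

  // traceback
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  char state;
  if (best == M[at(n, m)]) state = 'M';
  else if (best == X[at(n, m)]) state = 'X';
  else state = 'Y';
  while (i > 0 || j > 0) {
    if (i == 0) state = 'Y';
    else if (j == 0) state = 'X';
    if (state == 'M') {
      double s = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? match : mismatch;
      double target = M[at(i, j)] - s;
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[at(i, j)] == target) state = 'M';
      else if (X[at(i, j)] == target) state = 'X';
      else state = 'Y';
    } else if (state == 'X') {
      double target = X[at(i, j)];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i;
      if (M[at(i, j)] + gap_open + gap_extend == target) state = 'M';
      else if (X[at(i, j)] + gap_extend == target) state = 'X';
      else state = 'Y';
    } else {
      double target = Y[at(i, j)];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
      if (M[at(i, j)] + gap_open + gap_extend == target) state = 'M';
      else if (Y[at(i, j)] + gap_extend == target) state = 'Y';
      else state = 'X';
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = best);
}
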