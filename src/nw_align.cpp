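#include <Rcpp.h>
#include <string>
#include <vector>

// IUPAC bitmask; '-' and unknown -> 0 (never matches).
static inline int iupac_bits(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
    case 'M': return 3; case 'R': return 5; case 'W': return 9; case 'S': return 6;
    case 'Y': return 10; case 'K': return 12; case 'V': return 7; case 'H': return 11;
    case 'D': return 13; case 'B': return 14; case 'N': return 15;
    default: return 0;
  }
}

// Global alignment, linear gap penalty, set-intersection match semantics.
// Traceback tie-break: diagonal, then up (gap in b), then left (gap in a).
// [[Rcpp::export]]
Rcpp::List nw_align_cpp(std::string a, std::string b,
                        double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<int> ab(n), bb(m);
  for (int i = 0; i < n; ++i) ab[i] = iupac_bits(a[i]);
  for (int j = 0; j < m; ++j) bb[j] = iupac_bits(b[j]);

  std::vector<double> S((n + 1) * (m + 1));
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  for (int i = 0; i <= n; ++i) S[idx(i, 0)] = i * gap;
  for (int j = 0; j <= m; ++j) S[idx(0, j)] = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sub = S[idx(i - 1, j - 1)] +
                   (((ab[i - 1] & bb[j - 1]) != 0) ? match : mismatch);
      double up = S[idx(i - 1, j)] + gap;
      double lf = S[idx(i, j - 1)] + gap;
      double best = sub;
      if (up > best) best = up;
      if (lf > best) best = lf;
      S[idx(i, j)] = best;
    }
  }

  std::string ga, gb;
  ga.reserve(n + m);
  gb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      double sub = S[idx(i - 1, j - 1)] +
                   (((ab[i - 1] & bb[j - 1]) != 0) ? match : mismatch);
      if (S[idx(i, j)] == sub) {
        ga.push_back(a[i - 1]); gb.push_back(b[j - 1]); --i; --j; continue;
      }
    }
    if (i > 0 && S[idx(i, j)] == S[idx(i - 1, j)] + gap) {
      ga.push_back(a[i - 1]); gb.push_back('-'); --i; continue;
    }
    ga.push_back('-'); gb.push_back(b[j - 1]); --j;
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());

  return Rcpp::List::create(Rcpp::Named("score") = S[idx(n, m)],
                            Rcpp::Named("a") = ga,
                            Rcpp::Named("b") = gb);
}
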