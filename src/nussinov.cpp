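#include <Rcpp.h>
#include <vector>
#include <string>
#include <stack>
using namespace Rcpp;

// Per-pair energy model: e(G:C), e(A:U), e(G:U) in kcal/mol (all <= 0);
// 0 means "not pairable". Sequence must be upper-case RNA (ACGU).
static inline double pair_energy(char a, char b,
                                 double e_gc, double e_au, double e_gu) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return e_gc;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return e_au;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return e_gu;
  return 0.0;
}

// Minimum-energy nested structure by Nussinov-style dynamic programming,
// minimising the sum of per-pair energies subject to a minimum hairpin loop
// of `min_loop` unpaired bases. Among equal-energy structures the one with
// fewest pairs is chosen; remaining ties are resolved by a fixed traceback
// order (pair the left end with its largest admissible partner before
// leaving it unpaired), which is deterministic and keeps equal-energy
// stems contiguous (earliest possible '(' in the dot-bracket).
// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop,
                   double e_gc, double e_au, double e_gu) {
  const int n = (int) seq.size();
  IntegerVector partner(n, 0); // 1-based partner, 0 = unpaired
  if (n == 0)
    return List::create(_["mfe"] = 0.0, _["partner"] = partner,
                        _["npairs"] = 0);

  std::vector<double> E((size_t) n * n, 0.0);
  std::vector<int>    P((size_t) n * n, 0);
  #define IDX(i, j) ((size_t)(i) * (size_t)n + (size_t)(j))

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // option: i unpaired
      double bestE = E[IDX(i + 1, j)];
      int    bestP = P[IDX(i + 1, j)];
      // option: pair (i, k)
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double e = pair_energy(seq[i], seq[k], e_gc, e_au, e_gu);
        if (e >= 0.0) continue;
        double inner = (k - 1 >= i + 1) ? E[IDX(i + 1, k - 1)] : 0.0;
        double right = (k + 1 <= j) ? E[IDX(k + 1, j)] : 0.0;
        int pin = (k - 1 >= i + 1) ? P[IDX(i + 1, k - 1)] : 0;
        int prt = (k + 1 <= j) ? P[IDX(k + 1, j)] : 0;
        double cand = e + inner + right;
        int candP = 1 + pin + prt;
        if (cand < bestE - 1e-12 ||
            (std::abs(cand - bestE) <= 1e-12 && candP < bestP)) {
          bestE = cand;
          bestP = candP;
        }
      }
      E[IDX(i, j)] = bestE;
      P[IDX(i, j)] = bestP;
    }
  }

  // traceback
  std::stack<std::pair<int, int> > todo;
  todo.push(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.top().first, j = todo.top().second;
    todo.pop();
    if (i >= j || j - i < min_loop + 1) continue;
    double tgtE = E[IDX(i, j)];
    int    tgtP = P[IDX(i, j)];
    bool done = false;
    for (int k = j; k >= i + min_loop + 1 && !done; --k) {
      double e = pair_energy(seq[i], seq[k], e_gc, e_au, e_gu);
      if (e >= 0.0) continue;
      double inner = (k - 1 >= i + 1) ? E[IDX(i + 1, k - 1)] : 0.0;
      double right = (k + 1 <= j) ? E[IDX(k + 1, j)] : 0.0;
      int pin = (k - 1 >= i + 1) ? P[IDX(i + 1, k - 1)] : 0;
      int prt = (k + 1 <= j) ? P[IDX(k + 1, j)] : 0;
      if (std::abs(e + inner + right - tgtE) <= 1e-12 &&
          1 + pin + prt == tgtP) {
        partner[i] = k + 1;
        partner[k] = i + 1;
        todo.push(std::make_pair(i + 1, k - 1));
        todo.push(std::make_pair(k + 1, j));
        done = true;
      }
    }
    if (!done) todo.push(std::make_pair(i + 1, j));
  }
  #undef IDX

  int npairs = 0;
  for (int i = 0; i < n; ++i)
    if (partner[i] > i + 1) ++npairs;
  return List::create(_["mfe"] = E[(size_t) 0 * n + (n - 1)],
                      _["partner"] = partner, _["npairs"] = npairs);
}
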