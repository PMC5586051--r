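#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Secondary-structure prediction by a stacking-energy dynamic programme:
// Nussinov-style pseudoknot-free recursion that minimises the sum of
// nearest-neighbour stacking energies over helices (Turner-style stack
// weights supplied from R), with a minimum hairpin loop of `min_loop`
// unpaired bases.  Lone (unstacked) pairs contribute 0, so the optimum is
// always <= 0.  Energies are handled in integer units of 0.01 kcal/mol.

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': case 'U': return 3;
  default: return 4;
  }
}

// pair types 1..6 in the order CG, GC, GU, UG, AU, UA; 0 = not pairable
static inline int pair_type(int a, int b) {
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 2) return 4;
  if (a == 0 && b == 3) return 5;
  if (a == 3 && b == 0) return 6;
  return 0;
}

static const int INF = 1000000000;

// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(std::string seq, IntegerMatrix stack, int min_loop = 3) {
  int n = (int) seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = base_code(seq[i]);

  std::vector<std::vector<int> > W(n, std::vector<int>(n, 0));
  std::vector<std::vector<int> > V(n, std::vector<int>(n, INF));

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int tij = pair_type(s[i], s[j]);
      if (tij > 0) {
        // unstacked closing pair: interior folds freely
        int v = W[i + 1][j - 1];
        // stacked on inner pair (i+1, j-1)
        int tin = pair_type(s[j - 1], s[i + 1]); // inner pair, reversed
        if (tin > 0 && V[i + 1][j - 1] < INF) {
          int cand = stack(tij - 1, tin - 1) + V[i + 1][j - 1];
          if (cand < v) v = cand;
        }
        V[i][j] = v;
      }
      int w = W[i + 1][j];
      if (W[i][j - 1] < w) w = W[i][j - 1];
      if (V[i][j] < w) w = V[i][j];
      for (int k = i; k < j; ++k) {
        int cand = W[i][k] + W[k + 1][j];
        if (cand < w) w = cand;
      }
      W[i][j] = w;
    }
  }

  // traceback
  std::string db(n, '.');
  std::vector<std::pair<std::pair<int,int>, bool> > todo; // ((i,j), inV)
  if (n > 0) todo.push_back(std::make_pair(std::make_pair(0, n - 1), false));
  while (!todo.empty()) {
    int i = todo.back().first.first, j = todo.back().first.second;
    bool inV = todo.back().second;
    todo.pop_back();
    if (j - i <= min_loop) continue;
    if (inV) {
      db[i] = '(';
      db[j] = ')';
      int tij = pair_type(s[i], s[j]);
      int tin = pair_type(s[j - 1], s[i + 1]);
      if (tin > 0 && V[i + 1][j - 1] < INF &&
          V[i][j] == stack(tij - 1, tin - 1) + V[i + 1][j - 1]) {
        todo.push_back(std::make_pair(std::make_pair(i + 1, j - 1), true));
      } else {
        todo.push_back(std::make_pair(std::make_pair(i + 1, j - 1), false));
      }
      continue;
    }
    int w = W[i][j];
    if (w == W[i + 1][j]) {
      todo.push_back(std::make_pair(std::make_pair(i + 1, j), false));
    } else if (w == W[i][j - 1]) {
      todo.push_back(std::make_pair(std::make_pair(i, j - 1), false));
    } else if (V[i][j] < INF && w == V[i][j]) {
      todo.push_back(std::make_pair(std::make_pair(i, j), true));
    } else {
      for (int k = i; k < j; ++k) {
        if (w == W[i][k] + W[k + 1][j]) {
          todo.push_back(std::make_pair(std::make_pair(i, k), false));
          todo.push_back(std::make_pair(std::make_pair(k + 1, j), false));
          break;
        }
      }
    }
  }

  double mfe = (n > 0) ? W[0][n - 1] / 100.0 : 0.0;
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}
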