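#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Pair energies (kcal/mol) depend only on the unordered pair identity, so the
// model is symmetric: folding a sequence and its reverse complement gives the
// same minimum energy.
static inline double pair_energy(char a, char b, double e_gc, double e_au,
                                 double e_gu) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return e_gc;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return e_au;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return e_gu;
  return 1.0; // sentinel: not pairable (positive, never chosen)
}

static inline bool can_pair(char a, char b) {
  return pair_energy(a, b, -1, -1, -1) < 0;
}

// Energy-minimization fold with a hairpin-loop closing penalty.
//   C[i][j]  : minimum energy of i..j given (i,j) paired; an interior
//              without pairs is a hairpin loop and costs `loop_pen`, so
//              isolated single pairs are never favorable.
//   Ep[i][j] : minimum energy over structures of i..j with >= 1 pair.
//   E[i][j]  : min(0, Ep[i][j]) -- the empty structure is always allowed.
static const double INF = 1e9;

// [[Rcpp::export]]
List fold_cpp(std::string seq, double e_gc, double e_au, double e_gu,
              int min_loop, double loop_pen) {
  int n = seq.size();
  if (n == 0) return List::create(_["structure"] = "", _["mfe"] = 0.0);
  std::vector<std::vector<double> > E(n, std::vector<double>(n, 0.0));
  std::vector<std::vector<double> > Ep(n, std::vector<double>(n, INF));
  std::vector<std::vector<double> > C(n, std::vector<double>(n, INF));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double e = pair_energy(seq[i], seq[j], e_gc, e_au, e_gu);
      if (e < 0) {
        double inner = loop_pen; // empty interior: hairpin loop
        if (j - i - 1 >= min_loop + 2 && Ep[i + 1][j - 1] < loop_pen)
          inner = Ep[i + 1][j - 1];
        C[i][j] = e + inner;
      }
      double best = (i + 1 <= j) ? Ep[i + 1][j] : INF; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (C[i][k] >= INF / 2) continue;
        double outer = (k < j) ? E[k + 1][j] : 0.0;
        double cand = C[i][k] + outer;
        if (cand < best) best = cand;
      }
      Ep[i][j] = best;
      E[i][j] = best < 0 ? best : 0.0;
    }
  }
  // traceback over the three matrices; mode 0 = E, 1 = Ep, 2 = C
  std::string db(n, '.');
  std::vector<std::pair<std::pair<int, int>, int> > stack;
  stack.push_back(std::make_pair(std::make_pair(0, n - 1), 0));
  while (!stack.empty()) {
    int i = stack.back().first.first, j = stack.back().first.second;
    int mode = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    if (mode == 0) { // E: empty structure unless pairs strictly improve
      if (Ep[i][j] < 0)
        stack.push_back(std::make_pair(std::make_pair(i, j), 1));
      continue;
    }
    if (mode == 2) { // C: (i,j) is a pair
      db[i] = '(';
      db[j] = ')';
      if (j - i - 1 >= min_loop + 2 && Ep[i + 1][j - 1] < loop_pen)
        stack.push_back(std::make_pair(std::make_pair(i + 1, j - 1), 1));
      continue; // else: hairpin loop, interior stays unpaired
    }
    // Ep: leave i unpaired when that attains the optimum, else pair i
    if (i + 1 <= j && Ep[i + 1][j] < INF / 2 &&
        std::abs(Ep[i][j] - Ep[i + 1][j]) < 1e-9) {
      stack.push_back(std::make_pair(std::make_pair(i + 1, j), 1));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (C[i][k] >= INF / 2) continue;
      double outer = (k < j) ? E[k + 1][j] : 0.0;
      if (std::abs(Ep[i][j] - (C[i][k] + outer)) < 1e-9) {
        stack.push_back(std::make_pair(std::make_pair(i, k), 2));
        if (k < j)
          stack.push_back(std::make_pair(std::make_pair(k + 1, j), 0));
        break;
      }
    }
  }
  return List::create(_["structure"] = db, _["mfe"] = E[0][n - 1]);
}

// Intermolecular duplex: optimal non-crossing antiparallel pairing of two
// strands, unpaired bases free. b is taken 3'->5' so ordinary alignment
// recursion applies. Symmetric in argument order.
// [[Rcpp::export]]
double duplex_cpp(std::string a, std::string b, double e_gc, double e_au,
                  double e_gu) {
  int n = a.size(), m = b.size();
  std::string br(b.rbegin(), b.rend());
  std::vector<std::vector<double> > D(n + 1, std::vector<double>(m + 1, 0.0));
  for (int i = 1; i <= n; ++i) {
    for (int k = 1; k <= m; ++k) {
      double best = std::min(D[i - 1][k], D[i][k - 1]);
      double e = pair_energy(a[i - 1], br[k - 1], e_gc, e_au, e_gu);
      if (e < 0) best = std::min(best, D[i - 1][k - 1] + e);
      D[i][k] = best;
    }
  }
  return D[n][m];
}

// All genomic positions (0-based) where `tag` matches `contig` with at most
// max_mm substitutions; used by the internal short-read mapper.
// [[Rcpp::export]]
IntegerVector scan_matches_cpp(std::string contig, std::string tag, int max_mm) {
  int n = contig.size(), k = tag.size();
  std::vector<int> hits;
  for (int s = 0; s + k <= n; ++s) {
    int mm = 0;
    for (int p = 0; p < k; ++p) {
      if (contig[s + p] != tag[p] && ++mm > max_mm) break;
    }
    if (mm <= max_mm) hits.push_back(s);
  }
  return wrap(hits);
}
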