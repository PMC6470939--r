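#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Single stem-loop folding under the SLF-1 energy model.
//
// Energies are held in integer half-units (kcal/mol * -2 for pairs) so that
// ties are exact: GC/CG = -6, AT/TA = -4, GT/TG = -2, terminal-loop closure
// +6, each unpaired nucleotide interior to the stem +1.  A structure is a
// ladder of nested pairs (i1<i2<...<ik < jk<...<j1) with a terminal loop of
// at least 3 nt inside the innermost pair.  Ties in energy are broken toward
// more pairs, then by a fixed traceback preference that yields the
// lexicographically smallest pair list.

static const int INF = 1000000000;

static inline int pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -6;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return -4;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return -2;
  return INF;
}

struct Cell { int e; int np; };

static inline bool better(int e1, int np1, int e2, int np2) {
  // is (e1, np1) strictly better than (e2, np2)?
  if (e1 != e2) return e1 < e2;
  return np1 > np2;
}

// [[Rcpp::export(name = ".fold_slf1_cpp")]]
List fold_slf1_cpp(std::string seq, LogicalVector banned) {
  const int n = seq.size();
  if (n < 1) stop("empty sequence");
  std::vector<bool> ban(n, false);
  if (banned.size() == n) {
    for (int i = 0; i < n; ++i) ban[i] = banned[i] == TRUE;
  } else if (banned.size() != 0) {
    stop("constraint mask length must equal sequence length");
  }

  // D[i][j]: min energy of a stem whose outermost pair is (i, j)
  // U[i][j]: min energy of a structure strictly inside, charging +1 per
  //          skipped (unpaired) nucleotide at the current boundary
  std::vector<std::vector<Cell>> D(n, std::vector<Cell>(n, {INF, 0}));
  std::vector<std::vector<Cell>> U(n, std::vector<Cell>(n, {INF, 0}));
  std::vector<std::vector<signed char>> cD(n, std::vector<signed char>(n, -1));
  std::vector<std::vector<signed char>> cU(n, std::vector<signed char>(n, -1));

  for (int span = 0; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // D ---------------------------------------------------------------
      if (span >= 4 && !ban[i] && !ban[j]) {
        int pe = pair_energy(seq[i], seq[j]);
        if (pe < INF) {
          int be = INF, bn = 0; signed char ch = -1;
          // close with terminal loop (j - i - 1 >= 3 guaranteed by span >= 4)
          be = 6; bn = 0; ch = 0;
          Cell inner = U[i + 1][j - 1];
          if (inner.e < INF && better(inner.e, inner.np, be, bn)) {
            be = inner.e; bn = inner.np; ch = 1;
          }
          D[i][j].e = pe + be;
          D[i][j].np = bn + 1;
          cD[i][j] = ch;
        }
      }
      // U ---------------------------------------------------------------
      int be = INF, bn = 0; signed char ch = -1;
      if (D[i][j].e < INF) { be = D[i][j].e; bn = D[i][j].np; ch = 0; }
      if (i + 1 <= j && U[i + 1][j].e < INF) {
        int e = U[i + 1][j].e + 1, np = U[i + 1][j].np;
        if (better(e, np, be, bn)) { be = e; bn = np; ch = 1; }
      }
      if (j - 1 >= i && U[i][j - 1].e < INF) {
        int e = U[i][j - 1].e + 1, np = U[i][j - 1].np;
        if (better(e, np, be, bn)) { be = e; bn = np; ch = 2; }
      }
      U[i][j].e = be; U[i][j].np = bn; cU[i][j] = ch;
    }
  }

  // best outermost pair; prefer lower energy, more pairs, smaller i, smaller j
  int bi = -1, bj = -1, be = INF, bn = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 4; j < n; ++j) {
      if (D[i][j].e < INF &&
          (better(D[i][j].e, D[i][j].np, be, bn) ||
           (D[i][j].e == be && D[i][j].np == bn && bi == -1))) {
        be = D[i][j].e; bn = D[i][j].np; bi = i; bj = j;
      }
    }
  }

  if (bi < 0 || be >= 0) {
    return List::create(_["mfe"] = 0.0,
                        _["pairs"] = IntegerMatrix(0, 2),
                        _["loop"] = IntegerVector::create(NA_INTEGER, NA_INTEGER));
  }

  // traceback
  std::vector<std::pair<int, int>> pr;
  int i = bi, j = bj;
  bool inD = true;
  int loop_lo = -1, loop_hi = -1;
  while (true) {
    if (inD) {
      pr.push_back(std::make_pair(i + 1, j + 1));
      if (cD[i][j] == 0) { loop_lo = i + 2; loop_hi = j; break; }
      i += 1; j -= 1; inD = false;
    } else {
      signed char ch = cU[i][j];
      if (ch == 0) { inD = true; }
      else if (ch == 1) { i += 1; }
      else { j -= 1; }
    }
  }

  IntegerMatrix pm(pr.size(), 2);
  for (size_t k = 0; k < pr.size(); ++k) { pm(k, 0) = pr[k].first; pm(k, 1) = pr[k].second; }
  return List::create(_["mfe"] = be / 2.0,
                      _["pairs"] = pm,
                      _["loop"] = IntegerVector::create(loop_lo, loop_hi));
}
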