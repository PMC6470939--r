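#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Antiparallel complementarity scan of a miRNA (5'->3') against a transcript
// (5'->3').  miRNA position 1 pairs the 3'-most transcript position of the
// site (site_end); gaps are miRNA positions aligned opposite nothing on the
// transcript (the site is shorter than the miRNA).  Scores are additive
// per-position weights, doubled inside a seed window, held in integer
// half-units for exact ties.

static const int INF = 1000000000;

static inline int pair_class(char m, char t) {
  // 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch (DNA alphabet)
  if ((m == 'A' && t == 'T') || (m == 'T' && t == 'A') ||
      (m == 'G' && t == 'C') || (m == 'C' && t == 'G')) return 0;
  if ((m == 'G' && t == 'T') || (m == 'T' && t == 'G')) return 1;
  return 2;
}

// [[Rcpp::export(name = ".scan_sites_cpp")]]
DataFrame scan_sites_cpp(std::string mirna, std::string transcript,
                         double cutoff, int max_gaps,
                         int seed_lo, int seed_hi, double seed_factor,
                         double w_gu, double w_mismatch, double w_gap,
                         IntegerVector gap_banned) {
  const int L = mirna.size();
  const int T = transcript.size();
  const int G = max_gaps;
  const int cut = (int)(cutoff * 2 + 1e-6);
  std::vector<bool> ban(L + 1, false);
  for (int k = 0; k < gap_banned.size(); ++k) {
    int p = gap_banned[k];
    if (p >= 1 && p <= L) ban[p] = true;
  }
  // terminal gap columns would only re-delimit the site; keep gaps interior
  ban[1] = true;
  if (L >= 1) ban[L] = true;
  auto wt = [&](int p, int cls) -> int {
    double w = (cls == 0) ? 0.0 : (cls == 1 ? w_gu : w_mismatch);
    if (p >= seed_lo && p <= seed_hi) w *= seed_factor;
    return (int)(w * 2 + 1e-6);
  };
  auto wgap = [&](int p) -> int {
    double w = w_gap;
    if (p >= seed_lo && p <= seed_hi) w *= seed_factor;
    return (int)(w * 2 + 1e-6);
  };

  std::vector<int> out_end, out_start, out_gaps;
  std::vector<double> out_score;
  std::vector<std::string> out_pairing;

  // S[p][g], p = 0..L, g = 0..G; transcript consumed = p - g
  std::vector<std::vector<int>> S(L + 1, std::vector<int>(G + 1, INF));
  std::vector<std::vector<signed char>> back(L + 1, std::vector<signed char>(G + 1, -1));

  for (int j = 0; j < T; ++j) {           // site_end (0-based)
    for (int p = 0; p <= L; ++p)
      for (int g = 0; g <= G; ++g) { S[p][g] = INF; back[p][g] = -1; }
    S[0][0] = 0;
    for (int p = 1; p <= L; ++p) {
      for (int g = 0; g <= G && g < p; ++g) {
        int t = j - (p - g - 1);          // transcript index paired with p
        int best = INF; signed char ch = -1;
        if (t >= 0 && S[p - 1][g] < INF) {
          int cls = pair_class(mirna[p - 1], transcript[t]);
          int e = S[p - 1][g] + wt(p, cls);
          if (e < best) { best = e; ch = 0; }
        }
        if (g >= 1 && !ban[p] && S[p - 1][g - 1] < INF) {
          int e = S[p - 1][g - 1] + wgap(p);
          if (e < best) { best = e; ch = 1; }
        }
        S[p][g] = best; back[p][g] = ch;
      }
      // g == p impossible beyond deletions-only start; g < p enforced above
    }
    int best = INF, bg = -1;
    for (int g = 0; g <= G; ++g) {
      if (j - (L - g) + 1 < 0) continue;  // site must fit in transcript
      if (S[L][g] < best) { best = S[L][g]; bg = g; }
    }
    if (bg >= 0 && best <= cut) {
      // traceback for the pairing string (per miRNA position, 5'->3')
      std::string pairing(L, '?');
      int p = L, g = bg;
      while (p > 0) {
        signed char ch = back[p][g];
        if (ch == 0) {
          int t = j - (p - g - 1);
          int cls = pair_class(mirna[p - 1], transcript[t]);
          pairing[p - 1] = (cls == 0) ? '|' : (cls == 1 ? 'o' : '.');
          p -= 1;
        } else {
          pairing[p - 1] = '-';
          p -= 1; g -= 1;
        }
      }
      out_end.push_back(j + 1);
      out_start.push_back(j + 1 - (L - bg) + 1);
      out_gaps.push_back(bg);
      out_score.push_back(best / 2.0);
      out_pairing.push_back(pairing);
    }
  }
  return DataFrame::create(_["site_start"] = out_start,
                           _["site_end"] = out_end,
                           _["score"] = out_score,
                           _["n_gap"] = out_gaps,
                           _["pairing"] = out_pairing,
                           _["stringsAsFactors"] = false);
}
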