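// Expectation-penalty scan for miRNA target sites.
//
// A candidate site is a transcript window aligned antiparallel to the
// miRNA.  Per aligned miRNA position: Watson-Crick pair 0, G:U wobble 0.5,
// mismatch 1.0, gap 2.0; penalties are doubled inside the seed region
// (miRNA positions seed_start..seed_end).  The scan slides every window of
// length |miRNA| +/- max_gaps over the transcript and computes the optimal
// (minimum-expectation) banded alignment with at most max_gaps gaps.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static inline int code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return 4;
  }
}

// pair status: 0 = WC, 1 = GU wobble, 2 = mismatch
static inline int pair_status(int m, int t) {
  if ((m == 0 && t == 3) || (m == 3 && t == 0) ||
      (m == 1 && t == 2) || (m == 2 && t == 1)) return 0;
  if ((m == 2 && t == 3) || (m == 3 && t == 2)) return 1;
  return 2;
}

static const double PEN[3] = {0.0, 0.5, 1.0};
static const double GAP_PEN = 2.0;
static const double BIG = 1e18;

// [[Rcpp::export]]
DataFrame c_scan_transcript(std::string mirna, std::string transcript,
                            int max_gaps, double cutoff,
                            int seed_start, int seed_end) {
  std::vector<int> m;
  for (size_t i = 0; i < mirna.size(); ++i) m.push_back(code(mirna[i]));
  std::vector<int> tx;
  for (size_t i = 0; i < transcript.size(); ++i) tx.push_back(code(transcript[i]));
  int L = (int)m.size(), T = (int)tx.size(), G = max_gaps;

  std::vector<int> out_start, out_end;
  std::vector<double> out_exp;
  std::vector<std::string> out_maln, out_saln, out_ann;

  // seed multiplier for miRNA position p (1-based)
  std::vector<double> mult(L + 2, 1.0);
  for (int p = 1; p <= L + 1; ++p) {
    int q = std::min(p, L);
    mult[p] = (q >= seed_start && q <= seed_end) ? 2.0 : 1.0;
  }

  int d2 = (L + 1) * 1;  // helpers for flat indexing below
  for (int S = std::max(1, L - G); S <= L + G; ++S) {
    if (S > T) break;
    int band = std::abs(S - L);
    if (band > G) continue;
    std::vector<double> D((size_t)(G + 1) * (L + 1) * (S + 1), BIG);
    std::vector<signed char> from((size_t)(G + 1) * (L + 1) * (S + 1), -1);
    // from codes: 0 diag, 1 miRNA unpaired (gap in target), 2 target bulge
    #define IDX(g, i, j) ((size_t)(g) * (L + 1) * (S + 1) + (size_t)(i) * (S + 1) + (j))
    for (int start = 0; start + S <= T; ++start) {
      // reversed window: rs[k] pairs miRNA position k+1
      // rs[k] = tx[start + S - 1 - k]
      std::fill(D.begin(), D.end(), BIG);
      std::fill(from.begin(), from.end(), -1);
      D[IDX(0, 0, 0)] = 0.0;
      for (int g = 0; g <= G; ++g) {
        for (int i = 0; i <= L; ++i) {
          for (int j = 0; j <= S; ++j) {
            double cur = D[IDX(g, i, j)];
            if (cur >= BIG) continue;
            if (i < L && j < S) {
              int tb = tx[start + S - 1 - j];
              double c = cur + PEN[pair_status(m[i], tb)] * mult[i + 1];
              size_t id = IDX(g, i + 1, j + 1);
              if (c < D[id]) { D[id] = c; from[id] = 0; }
            }
            if (g < G && i < L) {  // miRNA base unpaired (gap in target)
              double c = cur + GAP_PEN * mult[i + 1];
              size_t id = IDX(g + 1, i + 1, j);
              if (c < D[id]) { D[id] = c; from[id] = 1; }
            }
            if (g < G && j < S) {  // extra target base (bulge)
              double c = cur + GAP_PEN * mult[i + 1];
              size_t id = IDX(g + 1, i, j + 1);
              if (c < D[id]) { D[id] = c; from[id] = 2; }
            }
          }
        }
      }
      double best = BIG;
      int best_g = -1;
      for (int g = 0; g <= G; ++g) {
        if (D[IDX(g, L, S)] < best) { best = D[IDX(g, L, S)]; best_g = g; }
      }
      if (best_g < 0 || best > cutoff + 1e-9) continue;
      // traceback
      std::string maln, saln, ann;
      int g = best_g, i = L, j = S;
      while (i > 0 || j > 0) {
        signed char f = from[IDX(g, i, j)];
        if (f == 0) {
          int tb = tx[start + S - 1 - (j - 1)];
          int st = pair_status(m[i - 1], tb);
          maln.push_back(mirna[i - 1]);
          saln.push_back(transcript[start + S - 1 - (j - 1)]);
          ann.push_back(st == 0 ? '|' : (st == 1 ? 'o' : ' '));
          --i; --j;
        } else if (f == 1) {
          maln.push_back(mirna[i - 1]);
          saln.push_back('-');
          ann.push_back('-');
          --i; --g;
        } else if (f == 2) {
          maln.push_back('-');
          saln.push_back(transcript[start + S - 1 - (j - 1)]);
          ann.push_back('-');
          --j; --g;
        } else {
          stop("traceback failure in target scan");
        }
      }
      std::reverse(maln.begin(), maln.end());
      std::reverse(saln.begin(), saln.end());
      std::reverse(ann.begin(), ann.end());
      out_start.push_back(start + 1);
      out_end.push_back(start + S);
      out_exp.push_back(best);
      out_maln.push_back(maln);
      out_saln.push_back(saln);
      out_ann.push_back(ann);
    }
    #undef IDX
  }
  (void)d2;
  return DataFrame::create(_["site_start"] = out_start,
                           _["site_end"] = out_end,
                           _["expectation"] = out_exp,
                           _["mirna_aln"] = out_maln,
                           _["site_aln"] = out_saln,
                           _["annotation"] = out_ann,
                           _["stringsAsFactors"] = false);
}
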