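// Minimum-free-energy RNA secondary structure prediction with a compact
// embedded nearest-neighbour model (37 C, 1 M NaCl regime by construction).
//
// Model components:
//   * stacking energies for the 6 canonical pair types (Watson-Crick + G:U),
//     indexed Vienna-style: E_stack(i,j;i+1,j-1) = STACK[type(i,j)][type(j-1,i+1)]
//   * hairpin / bulge / interior loop initiation, tabulated for small sizes
//     and extended by Jacobson-Stockmayer logarithmic extrapolation
//     (1.75 * RT * ln(n/n0) with RT = 0.6163 kcal/mol at 37 C)
//   * interior-loop asymmetry penalty (0.5 kcal per nt, capped at 3.0)
//   * affine multibranch penalty a + b * branches + c * unpaired
//   * no dangling ends, no coaxial stacking, no pseudoknots; N never pairs
//
// Energies are integers in units of 0.1 kcal/mol.  The DP optimises the
// combined objective energy*1024 + npairs so that among equal-energy
// structures one with fewer pairs is preferred; traceback choices are made
// in a fixed order so folding is fully deterministic.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

typedef long long ll;
static const ll INF = 4e15;
static const ll PAIR_SCALE = 1024;  // energy*1024 + pair count

// base codes: A=0 C=1 G=2 U=3 N=4
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    case 'N': case 'n': return 4;
    default: return -1;
  }
}

// pair types: 0 none, 1 CG, 2 GC, 3 GU, 4 UG, 5 AU, 6 UA
static inline int pair_type(int a, int b) {
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 2) return 4;
  if (a == 0 && b == 3) return 5;
  if (a == 3 && b == 0) return 6;
  return 0;
}

// stacking free energies, 0.1 kcal/mol; rows/cols CG GC GU UG AU UA.
// Symmetric under the (i,j;k,l) -> (l,k;j,i) convention used below.
static const int STACK[7][7] = {
  {0,   0,   0,   0,   0,   0,   0},
  {0, -24, -33, -21, -14, -21, -21},
  {0, -33, -34, -25, -15, -22, -24},
  {0, -21, -25,  13,  -5, -14, -13},
  {0, -14, -15,  -5,   3,  -6, -10},
  {0, -21, -22, -14,  -6, -11,  -9},
  {0, -21, -24, -13, -10,  -9, -13}
};

static const double RT_JS = 10.79;  // 1.75 * RT(37C) in 0.1 kcal units

static const int HAIRPIN_INIT[7] = {54, 56, 57, 54, 60, 55, 64};  // sizes 3..9
static const int BULGE_INIT[6]   = {38, 28, 32, 36, 40, 44};      // sizes 1..6
static const int INTERIOR_INIT[3] = {15, 16, 17};                 // sizes 2..4

static const int ML_CLOSE  = 34;  // multibranch closing penalty (a)
static const int ML_BRANCH = 4;   // per-branch penalty incl. closing (b)
static const int ML_UNPAIR = 0;   // per unpaired nt inside multiloop (c)
static const int ASYM_PER_NT = 5;
static const int ASYM_MAX = 30;

static inline int hairpin_energy(int n) {
  if (n < 3) return -1;  // caller treats as forbidden
  if (n <= 9) return HAIRPIN_INIT[n - 3];
  return HAIRPIN_INIT[6] + (int)std::lround(RT_JS * std::log((double)n / 9.0));
}

static inline int bulge_energy(int n) {
  if (n <= 6) return BULGE_INIT[n - 1];
  return BULGE_INIT[5] + (int)std::lround(RT_JS * std::log((double)n / 6.0));
}

static inline int interior_energy(int n) {
  if (n <= 4) return INTERIOR_INIT[n - 2];
  return INTERIOR_INIT[2] + (int)std::lround(RT_JS * std::log((double)n / 4.0));
}

// energy of the two-pair loop (i,j) enclosing (k,l): stack, bulge or interior
static inline int two_loop_energy(int n1, int n2, int t_out_rev, int t_in_rev) {
  if (n1 == 0 && n2 == 0) return STACK[t_out_rev][t_in_rev];
  if (n1 == 0 || n2 == 0) return bulge_energy(n1 + n2);
  int asym = ASYM_PER_NT * std::abs(n1 - n2);
  if (asym > ASYM_MAX) asym = ASYM_MAX;
  return interior_energy(n1 + n2) + asym;
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) stop("illegal residue '%s' at position %d", std::string(1, s[i]), (int)i + 1);
    v[i] = c;
  }
  return v;
}

struct FoldDP {
  int n, max_loop;
  std::vector<int> s;
  std::vector<ll> V, WM;
  std::vector<ll> W;

  ll& v(int i, int j) { return V[(size_t)i * n + j]; }
  ll& wm(int i, int j) { return WM[(size_t)i * n + j]; }

  int ptype(int i, int j) const {
    return pair_type(s[i], s[j]);
  }
  // reversed orientation type for the Vienna stack convention
  int ptype_rev(int i, int j) const { return pair_type(s[j], s[i]); }

  bool can_pair(int i, int j) const {
    return j - i >= 4 && ptype(i, j) != 0;  // hairpin loop >= 3
  }

  void run() {
    V.assign((size_t)n * n, INF);
    WM.assign((size_t)n * n, INF);
    for (int span = 4; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // --- V(i,j)
        if (can_pair(i, j)) {
          ll best = (ll)hairpin_energy(j - i - 1) * PAIR_SCALE + 1;
          // interior / bulge / stack to inner pair (k,l)
          for (int k = i + 1; k < j - 4; ++k) {
            int n1 = k - i - 1;
            if (n1 > max_loop) break;
            for (int l = j - 1; l > k + 3; --l) {
              int n2 = j - l - 1;
              if (n1 + n2 > max_loop) break;
              ll inner = v(k, l);
              if (inner >= INF) continue;
              int e = two_loop_energy(n1, n2, ptype(i, j), ptype_rev(k, l));
              ll cand = (ll)e * PAIR_SCALE + inner + 1;
              if (cand < best) best = cand;
            }
          }
          // multibranch closing: a + b + WM(i+1,k) + WM(k+1,j-1)
          for (int k = i + 1; k < j - 1; ++k) {
            ll l1 = wm(i + 1, k), l2 = wm(k + 1, j - 1);
            if (l1 >= INF || l2 >= INF) continue;
            ll cand = (ll)(ML_CLOSE + ML_BRANCH) * PAIR_SCALE + l1 + l2 + 1;
            if (cand < best) best = cand;
          }
          v(i, j) = best;
        }
        // --- WM(i,j): >= 1 branch inside a multiloop
        ll best = INF;
        if (wm(i + 1, j) < INF) best = std::min(best, wm(i + 1, j) + (ll)ML_UNPAIR * PAIR_SCALE);
        if (j - 1 >= i && wm(i, j - 1) < INF) best = std::min(best, wm(i, j - 1) + (ll)ML_UNPAIR * PAIR_SCALE);
        if (v(i, j) < INF) best = std::min(best, v(i, j) + (ll)ML_BRANCH * PAIR_SCALE);
        for (int k = i; k < j; ++k) {
          if (wm(i, k) < INF && wm(k + 1, j) < INF)
            best = std::min(best, wm(i, k) + wm(k + 1, j));
        }
        wm(i, j) = best;
      }
    }
    // exterior loop
    W.assign(n + 1, 0);
    for (int j = 1; j <= n; ++j) {
      ll best = W[j - 1];
      for (int i = 1; i <= j; ++i) {
        ll vij = v(i - 1, j - 1);
        if (vij < INF && W[i - 1] + vij < best) best = W[i - 1] + vij;
      }
      W[j] = best;
    }
  }

  // deterministic traceback; fills partner (-1 unpaired)
  void traceback(std::vector<int>& partner) {
    partner.assign(n, -1);
    // exterior
    int j = n;
    std::vector<std::pair<std::pair<int,int>,int> > stack;  // ((i,j), state) state 0=V 1=WM
    while (j > 0) {
      if (W[j] == W[j - 1]) { --j; continue; }
      bool found = false;
      for (int i = 1; i <= j && !found; ++i) {
        ll vij = v(i - 1, j - 1);
        if (vij < INF && W[i - 1] + vij == W[j]) {
          stack.push_back(std::make_pair(std::make_pair(i - 1, j - 1), 0));
          j = i - 1;
          found = true;
        }
      }
      if (!found) stop("traceback failure in exterior loop");
    }
    while (!stack.empty()) {
      int i = stack.back().first.first, jj = stack.back().first.second;
      int state = stack.back().second;
      stack.pop_back();
      if (state == 0) {
        partner[i] = jj; partner[jj] = i;
        ll target = v(i, jj);
        if (target == (ll)hairpin_energy(jj - i - 1) * PAIR_SCALE + 1) continue;
        bool found = false;
        for (int k = i + 1; k < jj - 4 && !found; ++k) {
          int n1 = k - i - 1;
          if (n1 > max_loop) break;
          for (int l = jj - 1; l > k + 3; --l) {
            int n2 = jj - l - 1;
            if (n1 + n2 > max_loop) break;
            ll inner = v(k, l);
            if (inner >= INF) continue;
            int e = two_loop_energy(n1, n2, ptype(i, jj), ptype_rev(k, l));
            if ((ll)e * PAIR_SCALE + inner + 1 == target) {
              stack.push_back(std::make_pair(std::make_pair(k, l), 0));
              found = true;
              break;
            }
          }
        }
        if (found) continue;
        for (int k = i + 1; k < jj - 1 && !found; ++k) {
          ll l1 = wm(i + 1, k), l2 = wm(k + 1, jj - 1);
          if (l1 >= INF || l2 >= INF) continue;
          if ((ll)(ML_CLOSE + ML_BRANCH) * PAIR_SCALE + l1 + l2 + 1 == target) {
            stack.push_back(std::make_pair(std::make_pair(i + 1, k), 1));
            stack.push_back(std::make_pair(std::make_pair(k + 1, jj - 1), 1));
            found = true;
          }
        }
        if (!found) stop("traceback failure in V");
      } else {
        ll target = wm(i, jj);
        if (wm(i + 1, jj) < INF && wm(i + 1, jj) + (ll)ML_UNPAIR * PAIR_SCALE == target) {
          stack.push_back(std::make_pair(std::make_pair(i + 1, jj), 1));
          continue;
        }
        if (jj - 1 >= i && wm(i, jj - 1) < INF && wm(i, jj - 1) + (ll)ML_UNPAIR * PAIR_SCALE == target) {
          stack.push_back(std::make_pair(std::make_pair(i, jj - 1), 1));
          continue;
        }
        if (v(i, jj) < INF && v(i, jj) + (ll)ML_BRANCH * PAIR_SCALE == target) {
          stack.push_back(std::make_pair(std::make_pair(i, jj), 0));
          continue;
        }
        bool found = false;
        for (int k = i; k < jj && !found; ++k) {
          if (wm(i, k) < INF && wm(k + 1, jj) < INF && wm(i, k) + wm(k + 1, jj) == target) {
            stack.push_back(std::make_pair(std::make_pair(i, k), 1));
            stack.push_back(std::make_pair(std::make_pair(k + 1, jj), 1));
            found = true;
          }
        }
        if (!found) stop("traceback failure in WM");
      }
    }
  }
};

// [[Rcpp::export]]
List c_fold(std::string sequence, int max_loop_size) {
  FoldDP dp;
  dp.s = encode(sequence);
  dp.n = (int)dp.s.size();
  dp.max_loop = max_loop_size;
  if (dp.n < 10) stop("sequence shorter than 10 nt cannot be folded");
  if (dp.n > 1000) stop("sequence longer than 1000 nt not supported");
  dp.run();
  std::vector<int> partner;
  dp.traceback(partner);
  ll comb = dp.W[dp.n];
  // decode energy from combined objective: comb = E * 1024 + npairs
  ll e10 = (ll)std::floor((double)comb / PAIR_SCALE);
  // exact floor division for negatives
  e10 = comb >= 0 ? comb / PAIR_SCALE : -(((-comb) + PAIR_SCALE - 1) / PAIR_SCALE);
  std::string db(dp.n, '.');
  int npairs = 0;
  for (int i = 0; i < dp.n; ++i) {
    if (partner[i] > i) { db[i] = '('; db[partner[i]] = ')'; ++npairs; }
  }
  IntegerMatrix pairs(npairs, 2);
  int r = 0;
  for (int i = 0; i < dp.n; ++i) {
    if (partner[i] > i) { pairs(r, 0) = i + 1; pairs(r, 1) = partner[i] + 1; ++r; }
  }
  return List::create(_["energy10"] = (int)e10,
                      _["dotbracket"] = db,
                      _["pairs"] = pairs);
}

// Free energy of an explicit structure under the same model; NA if the
// structure violates a hard constraint (non-canonical pair, hairpin < 3,
// crossing pairs, interior/bulge loop above max_loop_size).
// [[Rcpp::export]]
SEXP c_eval_structure(std::string sequence, IntegerMatrix pairs, int max_loop_size) {
  std::vector<int> s = encode(sequence);
  int n = (int)s.size();
  std::vector<int> partner(n, -1);
  for (int r = 0; r < pairs.nrow(); ++r) {
    int i = pairs(r, 0) - 1, j = pairs(r, 1) - 1;
    if (i < 0 || j >= n || i >= j) return IntegerVector::create(NA_INTEGER);
    if (partner[i] != -1 || partner[j] != -1) return IntegerVector::create(NA_INTEGER);
    if (pair_type(s[i], s[j]) == 0 || j - i < 4) return IntegerVector::create(NA_INTEGER);
    partner[i] = j; partner[j] = i;
  }
  // crossing check
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i) {
      for (int k = i + 1; k < partner[i]; ++k) {
        if (partner[k] >= 0 && (partner[k] < i || partner[k] > partner[i]))
          return IntegerVector::create(NA_INTEGER);
      }
    }
  }
  // recursive loop decomposition via explicit stack of closing pairs
  long long total = 0;
  std::vector<std::pair<int,int> > closings;
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i) { closings.push_back(std::make_pair(i, partner[i])); i = partner[i]; continue; }
  }
  // walk every closing pair (top-level ones seed the stack)
  std::vector<std::pair<int,int> > work(closings);
  while (!work.empty()) {
    int i = work.back().first, j = work.back().second;
    work.pop_back();
    // children: maximal pairs strictly inside (i,j)
    std::vector<std::pair<int,int> > ch;
    int unpaired = 0;
    for (int k = i + 1; k < j; ++k) {
      if (partner[k] > k) { ch.push_back(std::make_pair(k, partner[k])); k = partner[k]; }
      else ++unpaired;
    }
    if (ch.empty()) {
      total += hairpin_energy(j - i - 1);
    } else if (ch.size() == 1) {
      int k = ch[0].first, l = ch[0].second;
      int n1 = k - i - 1, n2 = j - l - 1;
      if (n1 + n2 > max_loop_size) return IntegerVector::create(NA_INTEGER);
      total += two_loop_energy(n1, n2, pair_type(s[i], s[j]), pair_type(s[l], s[k]));
      work.push_back(ch[0]);
    } else {
      total += ML_CLOSE + ML_BRANCH * (int)(ch.size() + 1) + ML_UNPAIR * unpaired;
      for (size_t c = 0; c < ch.size(); ++c) work.push_back(ch[c]);
    }
  }
  return IntegerVector::create((int)total);
}

// Nussinov-style maximum number of non-crossing canonical pairs
// (G:U allowed, hairpin loops >= 3 nt).
// [[Rcpp::export]]
int c_max_pairing(std::string sequence) {
  std::vector<int> s = encode(sequence);
  int n = (int)s.size();
  if (n == 0) return 0;
  std::vector<int> M((size_t)n * n, 0);
  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[(size_t)i * n + j - 1];  // j unpaired
      for (int k = i; k < j - 3; ++k) {
        if (pair_type(s[k], s[j]) != 0) {
          int left = (k > i) ? M[(size_t)i * n + k - 1] : 0;
          int inner = M[(size_t)(k + 1) * n + j - 1];
          if (left + inner + 1 > best) best = left + inner + 1;
        }
      }
      M[(size_t)i * n + j] = best;
    }
  }
  return M[(size_t)0 * n + n - 1];
}
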