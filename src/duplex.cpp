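#include <Rcpp.h>
using namespace Rcpp;

// Base encoding: A=0, C=1, G=2, U=3 (set in R by rna_to_int()).
// Pair types (5' base of the miRNA strand first):
// 0 AU, 1 UA, 2 CG, 3 GC, 4 GU, 5 UG; -1 = not pairable.
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

static const double BIG = 1e18;

// Minimum free energy of an intermolecular duplex between a miRNA (5'->3')
// and a sense-strand window, paired antiparallel (window read 3'->5').
// States: H[i][j] = best energy of a duplex whose last base pair is
// (mirna i, reversed-window j); extension by a stack (adjacent pair) uses the
// nearest-neighbour table, extension across unpaired bases pays an affine
// bulge/internal-loop penalty loop_open + loop_ext * n_unpaired.
// P[i][j] = min over i'<=i, j'<=j of H[i'][j'] + loop_ext*((i-i')+(j-j'))
// makes the affine-loop minimization O(n*m). No intramolecular structure.
static double dp_energy(const std::vector<int>& a, const std::vector<int>& b,
                        const NumericMatrix& stacks, double init,
                        double loop_open, double loop_ext) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<double> H((size_t)n * m, BIG), P((size_t)n * m, BIG);
  double best = BIG;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      const int pt = pair_type(a[i], b[j]);
      double h = BIG;
      if (pt >= 0) {
        h = init;  // open a new duplex at this pair
        if (i > 0 && j > 0) {
          const double hprev = H[(size_t)(i - 1) * m + (j - 1)];
          if (hprev < BIG / 2) {
            const int ps = pair_type(a[i - 1], b[j - 1]);
            if (ps >= 0) h = std::min(h, hprev + stacks(ps, pt));
          }
          const double pprev = P[(size_t)(i - 1) * m + (j - 1)];
          if (pprev < BIG / 2) h = std::min(h, pprev + loop_open);
        }
      }
      H[(size_t)i * m + j] = h;
      double p = h;
      if (i > 0) p = std::min(p, P[(size_t)(i - 1) * m + j] + loop_ext);
      if (j > 0) p = std::min(p, P[(size_t)i * m + (j - 1)] + loop_ext);
      P[(size_t)i * m + j] = p;
      if (h < best) best = h;
    }
  }
  if (best >= BIG / 2 || best >= 0.0) return 0.0;  // no stable duplex
  return best;
}

// [[Rcpp::export(name = ".duplex_dp_energy_cpp")]]
double duplex_dp_energy_cpp(IntegerVector mirna, IntegerVector window,
                            NumericMatrix stacks, double init,
                            double loop_open, double loop_ext) {
  std::vector<int> a(mirna.begin(), mirna.end());
  std::vector<int> b(window.size());
  for (int j = 0; j < window.size(); ++j) b[j] = window[window.size() - 1 - j];
  return dp_energy(a, b, stacks, init, loop_open, loop_ext);
}

// Scan a transcript with fixed-length windows; returns the minimum-energy
// window (ties broken by smallest start). Starts step apart; a final window
// flush with the transcript end is always evaluated.
// [[Rcpp::export(name = ".duplex_scan_cpp")]]
List duplex_scan_cpp(IntegerVector mirna, IntegerVector transcript,
                     int window, int step, NumericMatrix stacks, double init,
                     double loop_open, double loop_ext) {
  const int L = transcript.size();
  std::vector<int> a(mirna.begin(), mirna.end());
  int w = window > L ? L : window;
  double best = 1.0; int best_start = 0; bool found = false;
  for (int s = 0; s <= L - w; s += step) {
    bool last = (s + step > L - w);
    std::vector<int> b(w);
    for (int j = 0; j < w; ++j) b[j] = transcript[s + w - 1 - j];
    double e = dp_energy(a, b, stacks, init, loop_open, loop_ext);
    if (!found || e < best) { best = e; best_start = s; found = true; }
    if (last && s < L - w) s = L - w - step;  // force flush-end window next
  }
  return List::create(_["energy"] = best, _["start"] = best_start,
                      _["end"] = best_start + w);
}

// Seed complementarity: slide the miRNA along the site (antiparallel), score
// only miRNA seed positions [seed_from, seed_to] (1-based), each WC match = 1,
// each GU wobble = wobble_weight, divided by seed length; maximum over offsets.
// [[Rcpp::export(name = ".seed_scan_cpp")]]
List seed_scan_cpp(IntegerVector mirna, IntegerVector site,
                   int seed_from, int seed_to, double wobble_weight) {
  const int n = mirna.size(), L = site.size();
  if (L < n) stop("site shorter than miRNA");
  const int span = seed_to - seed_from + 1;
  // reversed site: position j (0-based) is site[L-1-j]
  double best = 0.0; int best_off = 0;
  for (int off = 0; off <= L - n; ++off) {
    double sc = 0.0;
    for (int k = seed_from - 1; k <= seed_to - 1; ++k) {
      const int pt = pair_type(mirna[k], site[L - 1 - (off + k)]);
      if (pt == 0 || pt == 1 || pt == 2 || pt == 3) sc += 1.0;
      else if (pt == 4 || pt == 5) sc += wobble_weight;
    }
    sc /= span;
    if (sc > best) { best = sc; best_off = off; }
  }
  // footprint of the full miRNA on the sense strand for the best offset
  const int sense_end = L - best_off;          // exclusive, 0-based
  const int sense_start = sense_end - n;
  return List::create(_["score"] = best, _["start"] = sense_start,
                      _["end"] = sense_end);
}
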