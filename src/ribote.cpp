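#include <Rcpp.h>
using namespace Rcpp;

// Base-pair weights: GC=3, AU=2, GU=1 (DNA alphabet, U already mapped to T).
static inline int pair_weight(const char a, const char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

// Maximum weighted base-pairing score over all non-crossing structures with
// a minimum hairpin loop of `min_loop` unpaired nucleotides (Nussinov-style
// O(n^3) recursion). Returns the optimal total pair weight (>= 0).
// Columns are processed left to right with the previous column buffered so
// the innermost loop only touches contiguous memory.
// [[Rcpp::export(name = ".nussinov_score")]]
int nussinov_score(const std::string& seq, const int min_loop = 3) {
  const int n = (int) seq.size();
  if (n < min_loop + 2) return 0;
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) {
    switch (seq[i]) {
      case 'A': code[i] = 0; break;
      case 'C': code[i] = 1; break;
      case 'G': code[i] = 2; break;
      default:  code[i] = 3; break;  // T (U mapped upstream)
    }
  }
  static const int W[4][4] = {
    //        A  C  G  T
    /* A */ { 0, 0, 0, 2 },
    /* C */ { 0, 0, 3, 0 },
    /* G */ { 0, 3, 0, 1 },
    /* T */ { 2, 0, 1, 0 } };
  std::vector<int> M((size_t) n * n, 0);   // row-major, M[i*n+j]
  std::vector<int> col(n, 0);              // col[k] = M[k][j-1]
  std::vector<int> wk(n, 0);               // wk[k] = weight of pair (k, j)
  for (int j = 1; j < n; ++j) {
    for (int k = 0; k < n; ++k) col[k] = M[(size_t) k * n + (j - 1)];
    const int cj = code[j];
    const int kmax = j - min_loop - 1;
    for (int k = 0; k <= kmax; ++k) wk[k] = W[code[k]][cj];
    for (int i = kmax; i >= 0; --i) {
      const int* rowi = &M[(size_t) i * n];
      // k = i (no left part); a w = 0 term is a valid (unpaired) split, so
      // it can be included without branching: it never beats the optimum.
      int best = col[i];                   // j unpaired
      int cand0 = col[i + 1] + wk[i];
      if (cand0 > best) best = cand0;
      for (int k = i + 1; k <= kmax; ++k) {
        const int cand = rowi[k - 1] + col[k + 1] + wk[k];
        if (cand > best) best = cand;
      }
      M[(size_t) i * n + j] = best;
    }
  }
  return M[n - 1];
}

static inline double welch_t_stat(const double* x, const int nx,
                                  const double* y, const int ny) {
  double mx = 0.0, my = 0.0;
  for (int i = 0; i < nx; ++i) mx += x[i];
  for (int i = 0; i < ny; ++i) my += y[i];
  mx /= nx;
  my /= ny;
  double vx = 0.0, vy = 0.0;
  for (int i = 0; i < nx; ++i) vx += (x[i] - mx) * (x[i] - mx);
  for (int i = 0; i < ny; ++i) vy += (y[i] - my) * (y[i] - my);
  vx /= (nx - 1);
  vy /= (ny - 1);
  const double den = std::sqrt(vx / nx + vy / ny);
  if (den == 0.0) {
    if (mx == my) return 0.0;
    return (mx > my) ? R_PosInf : R_NegInf;
  }
  return (mx - my) / den;
}

// Null distribution for the resampling t-test: both groups are redrawn
// i.i.d. normal at the common (null) mean with each group's plug-in sd,
// and the Welch t recomputed. Returns the number of |t*| >= t_abs. Uses
// R's RNG so results follow set.seed().
// [[Rcpp::export(name = ".boot_t_count")]]
int boot_t_count(double sd_a, double sd_b, int na, int nb, int n_resamples,
                 double t_abs) {
  std::vector<double> xa(na), xb(nb);
  RNGScope scope;
  int count = 0;
  for (int r = 0; r < n_resamples; ++r) {
    for (int i = 0; i < na; ++i) xa[i] = sd_a > 0 ? sd_a * norm_rand() : 0.0;
    for (int i = 0; i < nb; ++i) xb[i] = sd_b > 0 ? sd_b * norm_rand() : 0.0;
    double t = welch_t_stat(xa.data(), na, xb.data(), nb);
    double at = std::fabs(t);
    if (ISNAN(t)) at = 0.0;
    if (at >= t_abs - 1e-12) ++count;
  }
  return count;
}
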