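#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Composite-likelihood scan kernel.
//
// Sites carry a precomputed null log-likelihood and one or two class
// indices into an escape-probability table (rows: pe grid, columns:
// frequency class). For a test position and sweep strength alpha, each
// site's escape probability pe = 1 - exp(-alpha * d) selects a table row
// by linear interpolation on the pe grid; the log composite-likelihood
// ratio sums log(P_sweep) - log(P_null) over sites within max_span.
// At pe = 1 the sweep model equals the background, so distant sites
// contribute exactly zero and can be skipped.

struct SiteData {
  std::vector<double> pos, null_ll;
  std::vector<int> tab, j1, j2;
};

static inline double site_loglik(double pe,
                                 const std::vector<const double*>& tabs,
                                 const std::vector<int>& tab_nrow,
                                 const std::vector<double>& pe_grid,
                                 int tab_id, int j1, int j2,
                                 double null_ll) {
  const double* T = tabs[tab_id];
  int nr = tab_nrow[tab_id];
  // locate pe in grid (grid covers [0, 1], increasing)
  int npe = (int)pe_grid.size();
  int lo = 0, hi = npe - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (pe_grid[mid] <= pe) lo = mid; else hi = mid;
  }
  double w = (pe - pe_grid[lo]) / (pe_grid[hi] - pe_grid[lo]);
  if (w < 0) w = 0; if (w > 1) w = 1;
  double p = (1.0 - w) * T[lo + (size_t)nr * j1] +
             w * T[hi + (size_t)nr * j1];
  if (j2 >= 0) {
    p += (1.0 - w) * T[lo + (size_t)nr * j2] +
         w * T[hi + (size_t)nr * j2];
  }
  if (p < 1e-300) p = 1e-300;
  return std::log(p) - null_ll;
}

static double scan_alpha(double tp, double alpha, const SiteData& S,
                         size_t i0, size_t i1,
                         const std::vector<const double*>& tabs,
                         const std::vector<int>& tab_nrow,
                         const std::vector<double>& pe_grid) {
  double ll = 0.0;
  for (size_t i = i0; i < i1; ++i) {
    double d = std::fabs(S.pos[i] - tp);
    double x = alpha * d;
    if (x > 30.0) continue;  // pe == 1 in doubles: zero contribution
    double pe = 1.0 - std::exp(-x);
    ll += site_loglik(pe, tabs, tab_nrow, pe_grid, S.tab[i], S.j1[i],
                      S.j2[i], S.null_ll[i]);
  }
  return ll;
}

// [[Rcpp::export]]
NumericMatrix clr_scan_cpp(NumericVector test_pos, NumericVector site_pos,
                           IntegerVector tab, IntegerVector j1,
                           IntegerVector j2, NumericVector null_ll,
                           List tables, NumericVector pe_grid,
                           NumericVector alpha_grid, double max_span,
                           bool refine) {
  int n_sites = site_pos.size();
  SiteData S;
  S.pos.assign(site_pos.begin(), site_pos.end());
  S.null_ll.assign(null_ll.begin(), null_ll.end());
  S.tab.assign(tab.begin(), tab.end());
  S.j1.assign(j1.begin(), j1.end());
  S.j2.assign(j2.begin(), j2.end());

  std::vector<const double*> tabs;
  std::vector<int> tab_nrow;
  std::vector<NumericMatrix> keep;  // prevent GC of SEXPs
  for (int t = 0; t < tables.size(); ++t) {
    NumericMatrix M = tables[t];
    keep.push_back(M);
    tabs.push_back(REAL(M));
    tab_nrow.push_back(M.nrow());
  }
  std::vector<double> peg(pe_grid.begin(), pe_grid.end());

  int n_test = test_pos.size();
  NumericMatrix out(n_test, 2);
  size_t lo = 0, hi = 0;
  for (int t = 0; t < n_test; ++t) {
    double tp = test_pos[t];
    while (lo < (size_t)n_sites && S.pos[lo] < tp - max_span) ++lo;
    if (hi < lo) hi = lo;
    while (hi < (size_t)n_sites && S.pos[hi] <= tp + max_span) ++hi;
    double best_ll = 0.0;  // null baseline
    int best_a = -1;
    for (int a = 0; a < alpha_grid.size(); ++a) {
      double ll = scan_alpha(tp, alpha_grid[a], S, lo, hi, tabs, tab_nrow,
                             peg);
      if (ll > best_ll) { best_ll = ll; best_a = a; }
    }
    double alpha_hat = (best_a >= 0) ? alpha_grid[best_a] : NA_REAL;
    if (refine && best_a >= 0) {
      // golden-section on log(alpha) between the neighbours of the best
      // grid value
      double la = std::log((best_a > 0) ? alpha_grid[best_a - 1]
                                        : alpha_grid[best_a] / 3.0);
      double lb = std::log((best_a < alpha_grid.size() - 1)
                               ? alpha_grid[best_a + 1]
                               : alpha_grid[best_a] * 3.0);
      const double gr = 0.6180339887498949;
      double c = lb - gr * (lb - la), d = la + gr * (lb - la);
      double fc = scan_alpha(tp, std::exp(c), S, lo, hi, tabs, tab_nrow,
                             peg);
      double fd = scan_alpha(tp, std::exp(d), S, lo, hi, tabs, tab_nrow,
                             peg);
      for (int it = 0; it < 18; ++it) {
        if (fc > fd) {
          lb = d; d = c; fd = fc;
          c = lb - gr * (lb - la);
          fc = scan_alpha(tp, std::exp(c), S, lo, hi, tabs, tab_nrow, peg);
        } else {
          la = c; c = d; fc = fd;
          d = la + gr * (lb - la);
          fd = scan_alpha(tp, std::exp(d), S, lo, hi, tabs, tab_nrow, peg);
        }
      }
      double lx = (fc > fd) ? c : d;
      double fx = (fc > fd) ? fc : fd;
      if (fx > best_ll) { best_ll = fx; alpha_hat = std::exp(lx); }
    }
    out(t, 0) = 2.0 * best_ll;
    out(t, 1) = alpha_hat;
  }
  return out;
}
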