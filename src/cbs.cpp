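#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Maximal circular-arc two-sample t statistic.
//
// Boundaries (i, j) with 0 <= i < j <= n define the arc x[i+1..j]
// (1-based); its complement wraps around the ends of the vector. Because
// |T| is symmetric in the two groups, enumerating the non-wrapping arcs
// covers every circular partition. Ties keep the smallest i, then the
// smallest j (first maximum in scan order).
//
// min_width constrains the linear pieces a split would create: the arc
// itself must span >= min_width bins and each non-empty flank (x[1..i],
// x[j+1..n]) must too.
//
// [[Rcpp::export]]
List cbs_max_arc(NumericVector x, int min_width = 1) {
  const int n = x.size();
  if (n < 4) stop("need at least 4 observations");
  if (min_width < 1) min_width = 1;

  std::vector<double> S(n + 1, 0.0), SS(n + 1, 0.0);
  for (int k = 0; k < n; ++k) {
    S[k + 1] = S[k] + x[k];
    SS[k + 1] = SS[k] + x[k] * x[k];
  }
  const double tot = S[n], tot2 = SS[n];
  const double var_all = tot2 - tot * tot / n;
  if (var_all <= 1e-14 * std::max(1.0, tot2)) {
    // zero-variance input: no contrast anywhere
    return List::create(_["i"] = 0, _["j"] = n, _["stat"] = 0.0);
  }

  double best = -1.0;
  int bi = 0, bj = n;
  for (int i = 0; i <= n - 1; ++i) {
    if (i != 0 && i < min_width) continue;
    for (int j = i + 1; j <= n; ++j) {
      const int k = j - i, rest = n - k;
      if (rest < 1) continue;
      if (k < min_width) continue;
      const int right = n - j;
      if (right != 0 && right < min_width) continue;

      const double s1 = S[j] - S[i];
      const double q1 = SS[j] - SS[i];
      const double m1 = s1 / k;
      const double m2 = (tot - s1) / rest;
      const double w1 = q1 - k * m1 * m1;
      const double w2 = (tot2 - q1) - rest * m2 * m2;
      double sp2 = (w1 + w2) / (n - 2);
      if (sp2 < 0) sp2 = 0;
      double t;
      if (sp2 <= 0) {
        t = (m1 == m2) ? 0.0 : std::numeric_limits<double>::infinity();
      } else {
        t = std::fabs(m1 - m2) / std::sqrt(sp2 * (1.0 / k + 1.0 / rest));
      }
      if (t > best) {
        best = t;
        bi = i;
        bj = j;
      }
    }
  }
  if (best < 0) {
    // no admissible arc under the min_width constraint
    return List::create(_["i"] = 0, _["j"] = n, _["stat"] = 0.0);
  }
  // restore the sign of the arc-minus-complement mean difference
  const double s1 = S[bj] - S[bi];
  const int k = bj - bi;
  const double diff = s1 / k - (tot - s1) / (n - k);
  double signed_t = (diff < 0) ? -best : best;
  return List::create(_["i"] = bi, _["j"] = bj, _["stat"] = signed_t);
}

// Count permutations whose max |T| reaches t_obs, with optional early
// stop once `stop_after` exceedances are seen (the permutation p-value
// is then already known to exceed the split threshold).
//
// perms: n_perm x n matrix of 1-based permutation indices built in R so
// that all randomness flows through R's RNG.
//
// [[Rcpp::export]]
List cbs_perm_count(NumericVector x, IntegerMatrix perms, double t_obs,
                    int min_width = 1, int stop_after = -1) {
  const int n = x.size(), n_perm = perms.nrow();
  if (perms.ncol() != n) stop("permutation matrix does not match x");
  int exceed = 0, used = 0;
  NumericVector xp(n);
  for (int p = 0; p < n_perm; ++p) {
    for (int k = 0; k < n; ++k) xp[k] = x[perms(p, k) - 1];
    List r = cbs_max_arc(xp, min_width);
    double t = std::fabs(as<double>(r["stat"]));
    ++used;
    if (t >= std::fabs(t_obs)) ++exceed;
    if (stop_after > 0 && exceed >= stop_after) break;
  }
  return List::create(_["exceed"] = exceed, _["used"] = used);
}
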