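#include <Rcpp.h>
#include <algorithm>

using namespace Rcpp;

// Bisection helpers over an already-sorted timestamp vector. The base-R
// findInterval re-validates sortedness of the (multi-million element)
// table on every call; these kernels skip the scan and, because query
// streams here are themselves (nearly) sorted, gallop from the previous
// hit instead of bisecting the whole table each time.

// first index with t[idx] > x, expanding around a hint
static inline R_xlen_t ub_hint(const double *t, R_xlen_t n, double x,
                               R_xlen_t hint) {
  if (hint < 0) hint = 0;
  if (hint > n) hint = n;
  R_xlen_t lo = hint, hi = hint, step = 1;
  while (hi < n && t[hi] <= x) { hi += step; step <<= 1; }
  if (hi > n) hi = n;
  step = 1;
  while (lo > 0 && t[lo - 1] > x) { lo -= step; step <<= 1; }
  if (lo < 0) lo = 0;
  return std::upper_bound(t + lo, t + hi, x) - t;
}

// first index with t[idx] >= x, expanding around a hint
static inline R_xlen_t lb_hint(const double *t, R_xlen_t n, double x,
                               R_xlen_t hint) {
  if (hint < 0) hint = 0;
  if (hint > n) hint = n;
  R_xlen_t lo = hint, hi = hint, step = 1;
  while (hi < n && t[hi] < x) { hi += step; step <<= 1; }
  if (hi > n) hi = n;
  step = 1;
  while (lo > 0 && t[lo - 1] >= x) { lo -= step; step <<= 1; }
  if (lo < 0) lo = 0;
  return std::lower_bound(t + lo, t + hi, x) - t;
}

// number of elements of sorted t that are <= x[i] (findInterval semantics)
// [[Rcpp::export(name = ".fi_sorted")]]
IntegerVector fi_sorted(NumericVector x, NumericVector t) {
  const R_xlen_t n = x.size(), nt = t.size();
  IntegerVector out(n);
  const double *tb = REAL(t);
  R_xlen_t hint = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    hint = ub_hint(tb, nt, x[i], hint);
    out[i] = (int)hint;
  }
  return out;
}

// number of elements of sorted t inside the closed interval [a[i], b[i]]
// [[Rcpp::export(name = ".count_in_closed")]]
IntegerVector count_in_closed(NumericVector a, NumericVector b,
                              NumericVector t) {
  const R_xlen_t n = a.size(), nt = t.size();
  IntegerVector out(n);
  const double *tb = REAL(t);
  R_xlen_t hlo = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const R_xlen_t lo = lb_hint(tb, nt, a[i], hlo);
    const R_xlen_t hi = ub_hint(tb, nt, b[i], lo);
    out[i] = (int)(hi - lo);
    hlo = lo;
  }
  return out;
}
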