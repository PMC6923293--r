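#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Per-locus Gaussian likelihood-ratio scan over ordered region pairs.
//
// For each permutation row (a permutation of region indices, 1-based; the
// identity row gives the observed scan) and each locus, ordered pairs are
// assigned to the four genotype combinations (2*g_target + g_partner);
// pairs with a missing call at either member are excluded. The LR is the
// profiled-variance Gaussian statistic n * log(sse_null / sse_alt) with the
// pooled MLE variances clamped to varFloor (a sigma^2 floor).
//
// Gt:    regions x loci integer matrix (transposed for locus-contiguous
//        access), values 0/1/NA.
// tidx:  1-based region index of the target of each ordered pair.
// pidx:  1-based region index of the partner.
// z:     derivative trait value per ordered pair.
// perms: n_perm x n_regions matrix; row = permuted region assignment.
// Returns an n_perm x n_loci matrix of LR values.
// [[Rcpp::export]]
NumericMatrix lr_scan_cpp(IntegerMatrix Gt, IntegerVector tidx,
                          IntegerVector pidx, NumericVector z,
                          IntegerMatrix perms, double varFloor) {
  const int R = Gt.nrow();
  const int L = Gt.ncol();
  const int P = tidx.size();
  const int nperm = perms.nrow();
  NumericMatrix out(nperm, L);
  std::vector<int> pt(P), pp(P);

  for (int pr = 0; pr < nperm; ++pr) {
    for (int i = 0; i < P; ++i) {
      pt[i] = perms(pr, tidx[i] - 1) - 1;
      pp[i] = perms(pr, pidx[i] - 1) - 1;
    }
    for (int l = 0; l < L; ++l) {
      const int *gl = &Gt[(size_t)l * R];
      double s[4] = {0, 0, 0, 0};
      double nc[4] = {0, 0, 0, 0};
      double s1 = 0, s2 = 0;
      int n = 0;
      for (int i = 0; i < P; ++i) {
        int gt = gl[pt[i]], gp = gl[pp[i]];
        if (gt == NA_INTEGER || gp == NA_INTEGER) continue;
        int c = 2 * gt + gp;
        double zi = z[i];
        s[c] += zi;
        nc[c] += 1.0;
        s1 += zi;
        s2 += zi * zi;
        ++n;
      }
      if (n < 2) { out(pr, l) = 0.0; continue; }
      double sseN = s2 - s1 * s1 / n;
      double sseA = s2;
      for (int c = 0; c < 4; ++c)
        if (nc[c] > 0) sseA -= s[c] * s[c] / nc[c];
      double fl = varFloor * n;
      if (sseN < fl) sseN = fl;
      if (sseA < fl) sseA = fl;
      double lr = (sseN <= 0 || sseA <= 0) ? 0.0 : n * std::log(sseN / sseA);
      out(pr, l) = lr > 0 ? lr : 0.0;
    }
  }
  return out;
}

// Combination counts for the observed assignment: rows = loci, columns =
// n_GG, n_GT, n_TG, n_TT, n_excluded. Gt as in lr_scan_cpp.
// [[Rcpp::export]]
IntegerMatrix combo_counts_cpp(IntegerMatrix Gt, IntegerVector tidx,
                               IntegerVector pidx) {
  const int R = Gt.nrow();
  const int L = Gt.ncol();
  const int P = tidx.size();
  IntegerMatrix out(L, 5);
  for (int l = 0; l < L; ++l) {
    const int *gl = &Gt[(size_t)l * R];
    for (int i = 0; i < P; ++i) {
      int gt = gl[tidx[i] - 1], gp = gl[pidx[i] - 1];
      if (gt == NA_INTEGER || gp == NA_INTEGER) { out(l, 4)++; continue; }
      out(l, 2 * gt + gp)++;
    }
  }
  return out;
}
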