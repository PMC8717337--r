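#include <Rcpp.h>
using namespace Rcpp;

// Independent-swap randomization (Gotelli & Entsminger 2001): repeatedly draw
// a random 2x2 submatrix and, iff it is a checkerboard, flip it. Preserves all
// row and column sums. Counts *successful* swaps, with a cap on attempts so a
// swap-free (e.g. perfectly nested) matrix terminates. Uses R's RNG so results
// are governed by set.seed().

// [[Rcpp::export]]
IntegerMatrix cpp_independent_swap(IntegerMatrix m, int n_swaps, int max_attempts) {
  IntegerMatrix out = clone(m);
  const int nr = out.nrow(), nc = out.ncol();
  int successes = 0;
  long attempts = 0;
  if (nr < 2 || nc < 2) {
    out.attr("swaps") = 0;
    out.attr("attempts") = 0;
    return out;
  }
  while (successes < n_swaps && attempts < (long)max_attempts) {
    ++attempts;
    int r1 = (int)(unif_rand() * nr);
    int r2 = (int)(unif_rand() * (nr - 1)); if (r2 >= r1) ++r2;
    int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * (nc - 1)); if (c2 >= c1) ++c2;
    const int a = out(r1, c1), b = out(r1, c2), c = out(r2, c1), d = out(r2, c2);
    if (a == 1 && d == 1 && b == 0 && c == 0) {
      out(r1, c1) = 0; out(r2, c2) = 0; out(r1, c2) = 1; out(r2, c1) = 1;
      ++successes;
    } else if (a == 0 && d == 0 && b == 1 && c == 1) {
      out(r1, c1) = 1; out(r2, c2) = 1; out(r1, c2) = 0; out(r2, c1) = 0;
      ++successes;
    }
  }
  out.attr("swaps") = successes;
  out.attr("attempts") = (int)attempts;
  return out;
}

// Per-site mean pairwise distance from a patristic distance matrix and a
// binary site x species matrix (columns aligned with d). NA for S < 2.

// [[Rcpp::export]]
NumericVector cpp_mpd(NumericMatrix d, IntegerMatrix comm) {
  const int ns = comm.nrow(), nsp = comm.ncol();
  NumericVector res(ns, NA_REAL);
  std::vector<int> idx;
  idx.reserve(nsp);
  for (int s = 0; s < ns; ++s) {
    idx.clear();
    for (int j = 0; j < nsp; ++j) if (comm(s, j) == 1) idx.push_back(j);
    const int S = (int)idx.size();
    if (S < 2) continue;
    double tot = 0.0;
    for (int i = 0; i < S; ++i)
      for (int j = i + 1; j < S; ++j)
        tot += d(idx[i], idx[j]);
    res[s] = tot / (S * (S - 1.0) / 2.0);
  }
  return res;
}

// Per-site mean nearest taxon distance. NA for S < 2.

// [[Rcpp::export]]
NumericVector cpp_mntd(NumericMatrix d, IntegerMatrix comm) {
  const int ns = comm.nrow(), nsp = comm.ncol();
  NumericVector res(ns, NA_REAL);
  std::vector<int> idx;
  idx.reserve(nsp);
  for (int s = 0; s < ns; ++s) {
    idx.clear();
    for (int j = 0; j < nsp; ++j) if (comm(s, j) == 1) idx.push_back(j);
    const int S = (int)idx.size();
    if (S < 2) continue;
    double tot = 0.0;
    for (int i = 0; i < S; ++i) {
      double mn = R_PosInf;
      for (int j = 0; j < S; ++j) {
        if (j == i) continue;
        const double v = d(idx[i], idx[j]);
        if (v < mn) mn = v;
      }
      tot += mn;
    }
    res[s] = tot / S;
  }
  return res;
}
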