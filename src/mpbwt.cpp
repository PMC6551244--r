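#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One sweep step: stable t-way counting sort of the prefix array keyed on the
// current column; divergence values travel with their haplotypes through the
// buckets, with a pending value p[l] per allele that is raised by every
// divergence seen since allele l last appeared.
static void advance_ad(const int* col, int M, int t, int k,
                       std::vector<int>& a, std::vector<int>& d, bool with_d) {
  std::vector< std::vector<int> > ab(t);
  std::vector< std::vector<int> > db;
  std::vector<int> p;
  if (with_d) { db.resize(t); p.assign(t, k + 1); }
  for (int i = 0; i < M; ++i) {
    int c = col[a[i]];
    if (c < 0 || c >= t)
      stop("allele code %d at site %d outside alphabet [0, %d)", c, k, t);
    if (with_d) {
      int di = d[i];
      for (int l = 0; l < t; ++l) if (di > p[l]) p[l] = di;
      db[c].push_back(p[c]);
      p[c] = 0;
    }
    ab[c].push_back(a[i]);
  }
  int pos = 0;
  for (int l = 0; l < t; ++l) {
    const std::vector<int>& al = ab[l];
    for (size_t j = 0; j < al.size(); ++j) {
      a[pos] = al[j];
      if (with_d) d[pos] = db[l][j];
      ++pos;
    }
  }
}

// [[Rcpp::export]]
List mpbwt_advance_cpp(IntegerVector a, IntegerVector d, IntegerVector column,
                       int t, int k, bool with_d) {
  int M = a.size();
  std::vector<int> av(a.begin(), a.end());
  std::vector<int> dv(M, 0);
  if (with_d) std::copy(d.begin(), d.end(), dv.begin());
  advance_ad(&column[0], M, t, k, av, dv, with_d);
  IntegerVector ra(av.begin(), av.end());
  if (with_d) {
    IntegerVector rd(dv.begin(), dv.end());
    return List::create(_["k"] = k + 1, _["a"] = ra, _["d"] = rd);
  }
  return List::create(_["k"] = k + 1, _["a"] = ra, _["d"] = R_NilValue);
}

// [[Rcpp::export]]
List mpbwt_build_cpp(IntegerMatrix X, IntegerVector tk, int keep, int stride) {
  // keep: 0 = all states, 1 = stride checkpoints plus final, 2 = final only
  int M = X.nrow(), N = X.ncol();
  std::vector<int> keep_sites;
  for (int k = 0; k <= N; ++k) {
    bool kp = (keep == 0) ||
              (keep == 1 && ((k % stride == 0) || k == N)) ||
              (keep == 2 && k == N);
    if (kp) keep_sites.push_back(k);
  }
  List A(keep_sites.size()), D(keep_sites.size());
  std::vector<int> a(M), d(M, 0), col(M);
  for (int i = 0; i < M; ++i) a[i] = i;
  size_t ki = 0;
  for (int k = 0; k <= N; ++k) {
    if (ki < keep_sites.size() && keep_sites[ki] == k) {
      A[ki] = IntegerVector(a.begin(), a.end());
      D[ki] = IntegerVector(d.begin(), d.end());
      ++ki;
    }
    if (k < N) {
      for (int i = 0; i < M; ++i) col[i] = X(i, k);
      advance_ad(col.data(), M, tk[k], k, a, d, true);
    }
  }
  IntegerVector kk(keep_sites.begin(), keep_sites.end());
  return List::create(_["k"] = kk, _["a"] = A, _["d"] = D);
}

static IntegerMatrix to_match_matrix(const std::vector<int>& out) {
  int n = (int)(out.size() / 4);
  IntegerMatrix m(n, 4);
  for (int r = 0; r < n; ++r) {
    m(r, 0) = out[4 * r];
    m(r, 1) = out[4 * r + 1];
    m(r, 2) = out[4 * r + 2];
    m(r, 3) = out[4 * r + 3];
  }
  return m;
}

// Block scan at one position: blocks of consecutive sorted haplotypes not
// separated by a divergence above the threshold; within a block, the start of
// a pair's match is the running maximum of divergence values between them.
// Interior sites (last = false): report cross-allele pairs (match terminates
// at k by mismatch). Last site (last = true): threshold is relaxed by one;
// same-allele pairs run to the panel end (end = N), cross-allele pairs are
// kept only if the segment before the last site already reaches length L.
// The final block is flushed by the virtual boundary at i = M.
static void report_long_at(const std::vector<int>& a, const std::vector<int>& d,
                           const int* col, int M, int k, int L, bool last,
                           int N, std::vector<int>& out) {
  int thresh = last ? (k - L + 1) : (k - L);
  int i0 = 0;
  for (int i = 1; i <= M; ++i) {
    bool boundary = (i == M) || (d[i] > thresh);
    if (!boundary) continue;
    if (i - i0 >= 2) {
      for (int ii = i0 + 1; ii < i; ++ii) {
        int yi = col[a[ii]];
        int dmax = 0;
        for (int jj = ii - 1; jj >= i0; --jj) {
          if (d[jj + 1] > dmax) dmax = d[jj + 1];
          int yj = col[a[jj]];
          if (!last) {
            if (yj != yi) {
              out.push_back(a[jj]); out.push_back(a[ii]);
              out.push_back(dmax);  out.push_back(k);
            }
          } else if (yj == yi) {
            out.push_back(a[jj]); out.push_back(a[ii]);
            out.push_back(dmax);  out.push_back(N);
          } else if (k - dmax >= L) {
            out.push_back(a[jj]); out.push_back(a[ii]);
            out.push_back(dmax);  out.push_back(k);
          }
        }
      }
    }
    i0 = i;
  }
}

// [[Rcpp::export]]
IntegerMatrix mpbwt_long_matches_at_cpp(IntegerVector a, IntegerVector d,
                                        IntegerVector column, int k, int L,
                                        bool last, int N) {
  int M = a.size();
  std::vector<int> av(a.begin(), a.end()), dv(d.begin(), d.end());
  std::vector<int> out;
  report_long_at(av, dv, &column[0], M, k, L, last, N, out);
  return to_match_matrix(out);
}

// [[Rcpp::export]]
IntegerMatrix mpbwt_long_matches_cpp(IntegerMatrix X, IntegerVector tk, int L) {
  int M = X.nrow(), N = X.ncol();
  std::vector<int> a(M), d(M, 0), col(M), out;
  for (int i = 0; i < M; ++i) a[i] = i;
  for (int k = 0; k < N; ++k) {
    for (int i = 0; i < M; ++i) col[i] = X(i, k);
    report_long_at(a, d, col.data(), M, k, L, k == N - 1, N, out);
    advance_ad(col.data(), M, tk[k], k, a, d, true);
  }
  return to_match_matrix(out);
}

// Divergence lookup with sentinels: positions 0 and M behave as "no neighbor"
// (a value larger than any attainable start).
static inline int dget(const std::vector<int>& d, int i, int M, int sent) {
  if (i <= 0 || i >= M) return sent;
  return d[i];
}

// Set-maximal reporting at an interior position k. The candidate match of the
// haplotype at sorted position i ends at k only if no haplotype within the
// equal-start neighbor range carries the same allele at k (otherwise the
// match extends and a longer one ends later). Matches of length 0 are not
// reported; on a tie between the two directions both sides are reported.
static void report_setmax_at(const std::vector<int>& a, const std::vector<int>& d,
                             const int* col, int M, int k, std::vector<int>& out) {
  int sent = k + 1;
  for (int i = 0; i < M; ++i) {
    int dl = dget(d, i, M, sent);
    int du = dget(d, i + 1, M, sent);
    int yi = col[a[i]];
    bool cont = false;
    int m = i - 1, n = i + 1;
    if (dl <= du) {
      while (dget(d, m + 1, M, sent) <= dl) {
        if (col[a[m]] == yi) { cont = true; break; }
        --m;
      }
    }
    if (!cont && du <= dl) {
      while (dget(d, n, M, sent) <= du) {
        if (col[a[n]] == yi) { cont = true; break; }
        ++n;
      }
    }
    if (cont) continue;
    if (dl <= du && dl < k) {
      for (int j = m + 1; j < i; ++j) {
        out.push_back(a[i]); out.push_back(a[j]);
        out.push_back(dl);   out.push_back(k);
      }
    }
    if (du <= dl && du < k) {
      for (int j = i + 1; j < n; ++j) {
        out.push_back(a[i]); out.push_back(a[j]);
        out.push_back(du);   out.push_back(k);
      }
    }
  }
}

// End-of-panel pass at k = N: every haplotype reports its longest matches
// running to the end (minimum-start neighbors, ties on both sides).
static void report_setmax_end(const std::vector<int>& a, const std::vector<int>& d,
                              int M, int N, std::vector<int>& out) {
  int sent = N + 1;
  for (int i = 0; i < M; ++i) {
    int dl = dget(d, i, M, sent);
    int du = dget(d, i + 1, M, sent);
    int s = std::min(dl, du);
    if (s >= N) continue;
    if (dl == s) {
      int m = i - 1;
      while (dget(d, m + 1, M, sent) <= s) {
        out.push_back(a[i]); out.push_back(a[m]);
        out.push_back(s);    out.push_back(N);
        --m;
      }
    }
    if (du == s) {
      int n = i + 1;
      while (dget(d, n, M, sent) <= s) {
        out.push_back(a[i]); out.push_back(a[n]);
        out.push_back(s);    out.push_back(N);
        ++n;
      }
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix mpbwt_set_maximal_cpp(IntegerMatrix X, IntegerVector tk) {
  int M = X.nrow(), N = X.ncol();
  std::vector<int> a(M), d(M, 0), col(M), out;
  for (int i = 0; i < M; ++i) a[i] = i;
  for (int k = 0; k < N; ++k) {
    for (int i = 0; i < M; ++i) col[i] = X(i, k);
    report_setmax_at(a, d, col.data(), M, k, out);
    advance_ad(col.data(), M, tk[k], k, a, d, true);
  }
  report_setmax_end(a, d, M, N, out);
  return to_match_matrix(out);
}

// [[Rcpp::export]]
List mpbwt_transform_cpp(IntegerMatrix X, IntegerVector tk, int a_stride) {
  int M = X.nrow(), N = X.ncol();
  std::vector<int> cp_sites;
  for (int k = 0; k < N; ++k) if (k % a_stride == 0) cp_sites.push_back(k);
  if (N == 0) cp_sites.push_back(0);
  IntegerMatrix Y(M, N);
  List cList(N), cpA(cp_sites.size());
  std::vector<int> a(M), d(M, 0), col(M);
  for (int i = 0; i < M; ++i) a[i] = i;
  size_t ci = 0;
  for (int k = 0; k < N; ++k) {
    if (ci < cp_sites.size() && cp_sites[ci] == k) {
      cpA[ci] = IntegerVector(a.begin(), a.end());
      ++ci;
    }
    int t = tk[k];
    IntegerVector cnt(t);
    for (int i = 0; i < M; ++i) {
      col[i] = X(i, k);
      int v = X(a[i], k);
      if (v < 0 || v >= t)
        stop("allele code %d at site %d outside alphabet [0, %d)", v, k, t);
      Y(i, k) = v;
      cnt[v] += 1;
    }
    cList[k] = cnt;
    advance_ad(col.data(), M, t, k, a, d, false);
  }
  if (N == 0) cpA[0] = IntegerVector(a.begin(), a.end());
  IntegerVector cps(cp_sites.begin(), cp_sites.end());
  return List::create(_["y"] = Y, _["c"] = cList,
                      _["cp_sites"] = cps, _["cp_a"] = cpA);
}
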