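# Brute-force reference implementations. Deliberately naive (quadratic or
# worse) and independent of the sweep code: these define the semantics the
# fast algorithms are tested against.

#' Brute-force prefix and divergence arrays at one position
#'
#' Sorts haplotypes by their reversed prefix at `k` with an explicit
#' multi-key stable sort (site `k - 1` is the most significant key) and
#' computes each divergence value directly as `k` minus the longest common
#' suffix length of the `k`-prefixes of sorted neighbors. Quadratic time;
#' exists purely as an independent oracle for [pbwt_build()].
#'
#' @param panel A [haplotype_panel].
#' @param k Position, `0 <= k <= N`.
#' @return A list with `k`, `a` (0-based prefix array) and `d` (divergence
#'   array with sentinel `d[0] = k`).
#' @export
oracle_sort <- function(panel, k) {
  assert_panel(panel)
  k <- as.integer(k)
  X <- panel$alleles
  M <- nrow(X)
  stopifnot(k >= 0L, k <= ncol(X))
  if (k == 0L) {
    return(list(k = 0L, a = seq_len(M) - 1L, d = integer(M)))
  }
  keys <- lapply(rev(seq_len(k)), function(j) X[, j])
  a <- do.call(order, c(keys, list(method = "radix"))) - 1L
  d <- integer(M)
  d[1] <- k
  if (M > 1L) {
    for (i in 2:M) {
      s1 <- X[a[i] + 1L, seq_len(k)]
      s2 <- X[a[i - 1L] + 1L, seq_len(k)]
      lcs <- 0L
      for (j in k:1) {
        if (s1[j] != s2[j]) break
        lcs <- lcs + 1L
      }
      d[i] <- k - lcs
    }
  }
  list(k = k, a = a, d = d)
}

# maximal shared segments between two allele vectors, as a matrix of
# (start, end) half-open 0-based rows
shared_segments <- function(x, y) {
  agree <- x == y
  if (!length(agree)) return(matrix(integer(0), 0, 2))
  r <- rle(agree)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  cbind(starts[keep], ends[keep])
}

#' Brute-force long-match oracle
#'
#' For every unordered pair of haplotypes, scans the agreement vector for
#' maximal runs and keeps those of length at least `L`. Defines the expected
#' output of [find_long_matches()].
#'
#' @param panel A [haplotype_panel].
#' @param L Minimum length in sites.
#' @return A canonical tibble of match records (see [canonicalize_matches()]).
#' @export
oracle_matches <- function(panel, L) {
  assert_panel(panel)
  L <- as.integer(L)
  stopifnot(L >= 1L)
  X <- panel$alleles
  M <- nrow(X)
  rows <- list()
  n <- 0L
  if (M >= 2L) {
    for (i in seq_len(M - 1L)) {
      for (j in (i + 1L):M) {
        seg <- shared_segments(X[i, ], X[j, ])
        if (nrow(seg)) {
          keep <- (seg[, 2] - seg[, 1]) >= L
          if (any(keep)) {
            n <- n + 1L
            rows[[n]] <- cbind(i - 1L, j - 1L, seg[keep, 1], seg[keep, 2])
          }
        }
      }
    }
  }
  m <- if (n) do.call(rbind, rows) else matrix(integer(0), 0, 4)
  canonicalize_matches(match_tibble(m, L))
}

#' Brute-force set-maximal oracle
#'
#' For each query haplotype, enumerates every maximal shared segment with
#' every other haplotype and keeps those not strictly contained in a longer
#' shared segment of the same query (with any haplotype). Zero-length
#' segments are excluded. Defines the expected output of
#' [set_maximal_matches()].
#'
#' @param panel A [haplotype_panel] with `M >= 2`.
#' @return A tibble of per-query match records (`hap_i` = query), sorted as
#'   [set_maximal_matches()] sorts.
#' @export
oracle_set_maximal <- function(panel) {
  assert_panel(panel)
  X <- panel$alleles
  M <- nrow(X)
  stopifnot(M >= 2L)
  rows <- list(); n <- 0L
  for (q in seq_len(M)) {
    segs <- list(); sn <- 0L
    for (j in seq_len(M)) {
      if (j == q) next
      seg <- shared_segments(X[q, ], X[j, ])
      if (nrow(seg)) {
        sn <- sn + 1L
        segs[[sn]] <- cbind(j - 1L, seg)
      }
    }
    if (!sn) next
    segs <- do.call(rbind, segs)
    segs <- segs[segs[, 3] - segs[, 2] > 0L, , drop = FALSE]
    if (!nrow(segs)) next
    len <- segs[, 3] - segs[, 2]
    keep <- vapply(seq_len(nrow(segs)), function(r) {
      !any(segs[, 2] <= segs[r, 2] & segs[, 3] >= segs[r, 3] & len > len[r])
    }, logical(1))
    segs <- segs[keep, , drop = FALSE]
    if (nrow(segs)) {
      n <- n + 1L
      rows[[n]] <- cbind(q - 1L, segs)
    }
  }
  m <- if (n) do.call(rbind, rows) else matrix(integer(0), 0, 4)
  out <- match_tibble(m, kind = "set_maximal")
  out <- dplyr::distinct(out)
  sort_matches(out)
}
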