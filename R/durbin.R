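# Independent bi-allelic reference: the classical two-bucket (u/v, p/q)
# formulation, written in plain R with scalars and appends rather than the
# t-way bucket machinery. On strictly bi-allelic panels the generalized
# sweep must reproduce these outputs exactly; kept naive on purpose.

assert_biallelic <- function(panel) {
  assert_panel(panel)
  if (any(panel$alphabet > 2L))
    stop("the bi-allelic reference needs alphabet sizes <= 2", call. = FALSE)
  invisible(panel)
}

#' Bi-allelic PBWT reference implementation
#'
#' `durbin_build()` constructs prefix and divergence arrays for a strictly
#' bi-allelic panel with the classical two-bucket update (`u`/`v` arrays and
#' scalar pending divergences `p`/`q`); `durbin_y()` returns the transformed
#' columns; `durbin_long_matches()` and `durbin_set_maximal()` are the
#' matching routines, including the corrected handling of matches that run to
#' the end of the panel. These are deliberately independent of the
#' generalized multi-allelic sweep and serve as its reference on `t = 2`
#' panels.
#'
#' @param panel A strictly bi-allelic [haplotype_panel].
#' @return `durbin_build()`: list with `k` (0..N), `a`, `d` (lists of 0-based
#'   arrays, divergence sentinel `d[0] = k`).
#' @export
durbin_build <- function(panel) {
  assert_biallelic(panel)
  X <- panel$alleles
  M <- nrow(X); N <- ncol(X)
  a <- seq_len(M) - 1L
  d <- integer(M)
  ks <- 0:N
  A <- vector("list", N + 1L); D <- vector("list", N + 1L)
  A[[1]] <- a; D[[1]] <- d
  for (k in seq_len(N)) {
    u <- integer(0); v <- integer(0)
    e <- integer(0); f <- integer(0)
    p <- k; q <- k  # pending starts (k = (k-1) + 1 in 0-based sweep terms)
    for (i in seq_len(M)) {
      hap <- a[i]
      if (d[i] > p) p <- d[i]
      if (d[i] > q) q <- d[i]
      if (X[hap + 1L, k] == 0L) {
        u <- c(u, hap); e <- c(e, p); p <- 0L
      } else {
        v <- c(v, hap); f <- c(f, q); q <- 0L
      }
    }
    a <- c(u, v)
    d <- c(e, f)
    A[[k + 1L]] <- a; D[[k + 1L]] <- d
  }
  list(k = ks, a = A, d = D)
}

#' @rdname durbin_build
#' @return `durbin_y()`: the `M x N` matrix with column `k` equal to the
#'   panel column permuted by `a_k`.
#' @export
durbin_y <- function(panel) {
  assert_biallelic(panel)
  b <- durbin_build(panel)
  X <- panel$alleles
  N <- ncol(X)
  Y <- matrix(0L, nrow = nrow(X), ncol = N)
  for (k in seq_len(N)) Y[, k] <- X[b$a[[k]] + 1L, k]
  Y
}

# report pairs within one block [i0, iend) of the sorted order; start of a
# pair is the maximum divergence strictly between their sorted positions
durbin_block_pairs <- function(a, d, y, i0, iend, k, L, last, N, acc) {
  if (iend - i0 < 2L) return(acc)
  for (ib in (i0 + 1L):(iend - 1L)) {
    for (ia in i0:(ib - 1L)) {
      start <- max(d[(ia + 2L):(ib + 1L)])  # d is 1-based storage
      if (!last) {
        if (y[ia + 1L] != y[ib + 1L])
          acc[[length(acc) + 1L]] <- c(a[ia + 1L], a[ib + 1L], start, k)
      } else if (y[ia + 1L] == y[ib + 1L]) {
        acc[[length(acc) + 1L]] <- c(a[ia + 1L], a[ib + 1L], start, N)
      } else if (k - start >= L) {
        acc[[length(acc) + 1L]] <- c(a[ia + 1L], a[ib + 1L], start, k)
      }
    }
  }
  acc
}

#' @rdname durbin_build
#' @param L Minimum match length in sites.
#' @return `durbin_long_matches()`: canonical tibble of all pairwise matches
#'   of length at least `L`.
#' @export
durbin_long_matches <- function(panel, L) {
  assert_biallelic(panel)
  L <- as.integer(L)
  stopifnot(L >= 1L)
  X <- panel$alleles
  M <- nrow(X); N <- ncol(X)
  b <- durbin_build(panel)
  acc <- list()
  for (k in seq_len(N) - 1L) {
    a <- b$a[[k + 1L]]; d <- b$d[[k + 1L]]
    y <- X[a + 1L, k + 1L]
    last <- k == N - 1L
    thresh <- if (last) k - L + 1L else k - L
    i0 <- 0L
    for (i in 1:M) {
      if (i == M || d[i + 1L] > thresh) {
        acc <- durbin_block_pairs(a, d, y, i0, i, k, L, last, N, acc)
        i0 <- i
      }
    }
  }
  m <- if (length(acc)) do.call(rbind, acc) else matrix(integer(0), 0, 4)
  canonicalize_matches(match_tibble(m, L))
}

#' @rdname durbin_build
#' @return `durbin_set_maximal()`: per-query tibble of set-maximal matches.
#' @export
durbin_set_maximal <- function(panel) {
  assert_biallelic(panel)
  X <- panel$alleles
  M <- nrow(X); N <- ncol(X)
  stopifnot(M >= 2L)
  b <- durbin_build(panel)
  acc <- list()
  dval <- function(d, i, sent) if (i <= 0L || i >= M) sent else d[i + 1L]
  for (k in seq_len(N) - 1L) {
    a <- b$a[[k + 1L]]; d <- b$d[[k + 1L]]
    y <- X[a + 1L, k + 1L]
    sent <- k + 1L
    for (i in seq_len(M) - 1L) {
      dl <- dval(d, i, sent); du <- dval(d, i + 1L, sent)
      cont <- FALSE
      m <- i - 1L; n <- i + 1L
      if (dl <= du) {
        while (dval(d, m + 1L, sent) <= dl) {
          if (y[m + 1L] == y[i + 1L]) { cont <- TRUE; break }
          m <- m - 1L
        }
      }
      if (!cont && du <= dl) {
        while (dval(d, n, sent) <= du) {
          if (y[n + 1L] == y[i + 1L]) { cont <- TRUE; break }
          n <- n + 1L
        }
      }
      if (cont) next
      if (dl <= du && dl < k && m + 1L <= i - 1L)
        for (j in (m + 1L):(i - 1L))
          acc[[length(acc) + 1L]] <- c(a[i + 1L], a[j + 1L], dl, k)
      if (du <= dl && du < k && i + 1L <= n - 1L)
        for (j in (i + 1L):(n - 1L))
          acc[[length(acc) + 1L]] <- c(a[i + 1L], a[j + 1L], du, k)
    }
  }
  # end of panel: longest matches running to N
  a <- b$a[[N + 1L]]; d <- b$d[[N + 1L]]
  sent <- N + 1L
  for (i in seq_len(M) - 1L) {
    dl <- dval(d, i, sent); du <- dval(d, i + 1L, sent)
    s <- min(dl, du)
    if (s >= N) next
    if (dl == s) {
      m <- i - 1L
      while (dval(d, m + 1L, sent) <= s) {
        acc[[length(acc) + 1L]] <- c(a[i + 1L], a[m + 1L], s, N)
        m <- m - 1L
      }
    }
    if (du == s) {
      n <- i + 1L
      while (dval(d, n, sent) <= s) {
        acc[[length(acc) + 1L]] <- c(a[i + 1L], a[n + 1L], s, N)
        n <- n + 1L
      }
    }
  }
  m <- if (length(acc)) do.call(rbind, acc) else matrix(integer(0), 0, 4)
  sort_matches(match_tibble(m, kind = "set_maximal"))
}
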