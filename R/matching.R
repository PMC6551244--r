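match_tibble <- function(m, L = NULL, kind = "long") {
  out <- tibble::tibble(hap_i = as.integer(m[, 1]), hap_j = as.integer(m[, 2]),
                        start = as.integer(m[, 3]), end = as.integer(m[, 4]),
                        length = as.integer(m[, 4] - m[, 3]))
  attr(out, "min_length") <- L
  attr(out, "kind") <- kind
  class(out) <- c("mpbwt_matches", class(out))
  out
}

sort_matches <- function(m) {
  m[order(m$end, m$start, m$hap_i, m$hap_j), , drop = FALSE]
}

#' Canonicalize match records
#'
#' Swaps haplotype indices so `hap_i < hap_j`, drops duplicate rows, and sorts
#' by `end`, `start`, `hap_i`, `hap_j`.
#'
#' @param matches A data frame of match records.
#' @return A tibble of canonical match records.
#' @export
canonicalize_matches <- function(matches) {
  i <- pmin(matches$hap_i, matches$hap_j)
  j <- pmax(matches$hap_i, matches$hap_j)
  out <- tibble::tibble(hap_i = i, hap_j = j,
                        start = matches$start, end = matches$end,
                        length = matches$end - matches$start)
  out <- dplyr::distinct(out)
  out <- sort_matches(out)
  class(out) <- c("mpbwt_matches", class(out))
  out
}

#' Report all pairwise matches of length at least L
#'
#' Finds every maximal shared segment of at least `L` sites between every
#' pair of haplotypes in the panel, in a single sweep. At each interior
#' position the sorted order groups candidate pairs into blocks not separated
#' by a divergence value above `k - L`; a pair is reported when its match
#' terminates, i.e. the two haplotypes carry different alleles at `k`. The
#' last site is handled separately so that matches running to the end of the
#' panel (including fully identical haplotype pairs) are reported as well —
#' the case a mismatch-terminated definition misses.
#'
#' "At least `L`" is inclusive: a match spanning exactly `L` sites is
#' reported.
#'
#' @param panel A [haplotype_panel].
#' @param L Minimum match length in sites (`1 <= L <= N`).
#' @return A tibble of class `mpbwt_matches` with columns `hap_i`, `hap_j`
#'   (0-based haplotype indices, `hap_i < hap_j`), `start`, `end` (0-based
#'   half-open site interval) and `length`, sorted by `end`, `start`,
#'   `hap_i`, `hap_j`.
#' @examples
#' p <- haplotype_panel(rbind(c(0L, 1L, 2L),
#'                            c(1L, 1L, 0L),
#'                            c(0L, 1L, 0L),
#'                            c(2L, 0L, 1L)))
#' find_long_matches(p, L = 2)
#' @export
find_long_matches <- function(panel, L) {
  assert_panel(panel)
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("`L` must be a positive integer", call. = FALSE)
  N <- ncol(panel$alleles)
  if (N == 0L) return(match_tibble(matrix(integer(0), 0, 4), L))
  m <- mpbwt_long_matches_cpp(panel$alleles, panel$alphabet, L)
  out <- canonicalize_matches(match_tibble(m, L))
  attr(out, "min_length") <- L
  out
}

#' Block-scan match reporting at a single position
#'
#' The per-position primitives behind [find_long_matches()], exposed for
#' inspection and testing. `long_matches_at()` reports matches of length at
#' least `L` terminating (by allele mismatch) at an interior position `k`;
#' `long_matches_last()` handles the final site `k = N - 1`, where blocks are
#' formed at threshold `k - L + 1` and the alleles at the last site decide
#' whether a pair's match ends at `N` (agreement) or must already have length
#' `L` before the last site (mismatch).
#'
#' @param state PBWT state at position `k` (list with `k`, `a`, `d`).
#' @param column Integer vector of length `M`: panel column `k`, indexed by
#'   haplotype.
#' @param L Minimum match length in sites.
#' @param N Total number of sites in the panel (for `long_matches_last()`).
#' @return A tibble of match records (not canonicalized: `hap_i`, `hap_j` in
#'   block-scan order).
#' @export
long_matches_at <- function(state, column, L) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("`L` must be a positive integer", call. = FALSE)
  m <- mpbwt_long_matches_at_cpp(as.integer(state$a), as.integer(state$d),
                                 as.integer(column), as.integer(state$k), L,
                                 FALSE, 0L)
  match_tibble(m, L)
}

#' @rdname long_matches_at
#' @export
long_matches_last <- function(state, column, L, N) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("`L` must be a positive integer", call. = FALSE)
  N <- as.integer(N)
  if (state$k != N - 1L)
    stop("`state` must be the PBWT at the last site (k = N - 1)", call. = FALSE)
  m <- mpbwt_long_matches_at_cpp(as.integer(state$a), as.integer(state$d),
                                 as.integer(column), as.integer(state$k), L,
                                 TRUE, N)
  match_tibble(m, L)
}

#' Report set-maximal matches
#'
#' For every haplotype `q`, reports the matches that are locally longest: a
#' shared segment `[start, end)` with some other haplotype such that it
#' cannot be extended in either direction and no other haplotype matches `q`
#' on a longer interval with the same endpoint. Matches reaching the end of
#' the panel are reported by a dedicated final pass, so identical haplotypes
#' yield their full-length matches. When several haplotypes tie for the
#' longest match, all of them are reported. Zero-length matches are never
#' reported.
#'
#' Records are per query: `hap_i` is the query haplotype and `hap_j` the
#' matched one, so a mutual longest match appears twice (once per query).
#' Use [canonicalize_matches()] for the deduplicated pair set.
#'
#' @param panel A [haplotype_panel] with at least two haplotypes.
#' @return A tibble of class `mpbwt_matches` with columns `hap_i` (query),
#'   `hap_j`, `start`, `end`, `length`, sorted by `end`, `start`, `hap_i`,
#'   `hap_j`.
#' @examples
#' p <- haplotype_panel(rbind(c(0L, 1L, 2L),
#'                            c(1L, 1L, 0L),
#'                            c(0L, 1L, 0L),
#'                            c(2L, 0L, 1L)))
#' set_maximal_matches(p)
#' @export
set_maximal_matches <- function(panel) {
  assert_panel(panel)
  if (nrow(panel$alleles) < 2L)
    stop("set-maximal matching needs at least two haplotypes", call. = FALSE)
  m <- mpbwt_set_maximal_cpp(panel$alleles, panel$alphabet)
  out <- match_tibble(m, kind = "set_maximal")
  sort_matches(out)
}
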