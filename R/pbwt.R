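#' Positional prefix and divergence arrays
#'
#' `pbwt_build()` sweeps the panel once, position by position, maintaining the
#' positional prefix array `a_k` (haplotype indices sorted by their reversed
#' prefix at `k`) and the divergence array `d_k` (`d_k[i]` is the 0-based site
#' where the maximal match between the haplotypes at sorted positions `i` and
#' `i - 1` begins). Each step is a stable counting sort over the site's
#' allele alphabet, so a site with `t_k` alleles costs `O(t_k + M)` for the
#' prefix array and `O(t_k * M)` with divergence updates. `d_k[0]` carries the
#' sentinel value `k`.
#'
#' `pbwt_init_state()` gives the state before the first site (`a_0` the
#' identity, `d_0` all zero) and `pbwt_advance()` performs one step, the
#' building block the matching and compression routines share.
#'
#' @param panel A [haplotype_panel].
#' @param keep Which states to retain: `"all"` (states `k = 0..N`,
#'   `N + 1` of them), `"checkpoints"` (every `stride`-th state plus the
#'   final one), or `"final"` (state `N` only).
#' @param stride Checkpoint stride in sites (default 32).
#' @return An object of class `pbwt`: a list with `k` (retained positions),
#'   `a` and `d` (lists of integer vectors, one per retained position), and
#'   the panel dimensions. Haplotype indices in `a` are 0-based.
#'
#' @examples
#' p <- haplotype_panel(rbind(c(0L, 1L, 2L),
#'                            c(1L, 1L, 0L),
#'                            c(0L, 1L, 0L),
#'                            c(2L, 0L, 1L)))
#' b <- pbwt_build(p)
#' pbwt_state(b, 3)
#' @export
pbwt_build <- function(panel, keep = c("all", "checkpoints", "final"),
                       stride = 32L) {
  assert_panel(panel)
  keep <- match.arg(keep)
  stride <- as.integer(stride)
  if (keep == "checkpoints" && stride < 1L)
    stop("`stride` must be a positive integer", call. = FALSE)
  code <- match(keep, c("all", "checkpoints", "final")) - 1L
  res <- mpbwt_build_cpp(panel$alleles, panel$alphabet, code,
                         max(stride, 1L))
  structure(list(k = res$k, a = res$a, d = res$d,
                 M = nrow(panel$alleles), N = ncol(panel$alleles),
                 alphabet = panel$alphabet, keep = keep, stride = stride),
            class = "pbwt")
}

#' @rdname pbwt_build
#' @param M Number of haplotypes.
#' @return `pbwt_init_state()`: a list with `k = 0`, `a` (identity
#'   permutation, 0-based) and `d` (all zero).
#' @export
pbwt_init_state <- function(M) {
  M <- as.integer(M)
  stopifnot(M >= 1L)
  list(k = 0L, a = seq_len(M) - 1L, d = integer(M))
}

#' @rdname pbwt_build
#' @param state A state list with elements `k`, `a` and (for divergence
#'   updates) `d`, as returned by `pbwt_init_state()`, `pbwt_advance()` or
#'   `pbwt_state()`.
#' @param column Integer vector of length `M`: the panel column at position
#'   `state$k`, indexed by haplotype (not by sorted position).
#' @param t_k Alphabet size at the site; codes `>= t_k` are an error.
#' @param divergence If `TRUE` (default) update the divergence array too;
#'   if `FALSE` only the prefix array is advanced and `d` is `NULL`.
#' @return `pbwt_advance()`: the state at `k + 1`.
#' @export
pbwt_advance <- function(state, column, t_k, divergence = TRUE) {
  stopifnot(is.list(state), !is.null(state$a))
  column <- as.integer(column)
  if (length(column) != length(state$a))
    stop("`column` must have one allele per haplotype", call. = FALSE)
  if (divergence && is.null(state$d))
    stop("state has no divergence array; use divergence = FALSE", call. = FALSE)
  mpbwt_advance_cpp(as.integer(state$a),
                    if (divergence) as.integer(state$d) else integer(0),
                    column, as.integer(t_k), as.integer(state$k), divergence)
}

#' @rdname pbwt_build
#' @param x A `pbwt` object.
#' @param k Sweep position of the wanted state (must be retained).
#' @return `pbwt_state()`: the state at position `k` as a list `k`, `a`, `d`.
#' @export
pbwt_state <- function(x, k) {
  stopifnot(inherits(x, "pbwt"))
  i <- match(as.integer(k), x$k)
  if (is.na(i))
    stop(sprintf("state at k = %d was not retained (keep = \"%s\")",
                 as.integer(k), x$keep), call. = FALSE)
  list(k = x$k[i], a = x$a[[i]], d = x$d[[i]])
}

#' @exportS3Method base::print
print.pbwt <- function(x, ...) {
  cat(sprintf("<pbwt> %d haplotypes x %d sites; %d retained state(s) (keep = \"%s\")\n",
              x$M, x$N, length(x$k), x$keep))
  invisible(x)
}

#' Tidy and summary methods for PBWT objects
#'
#' `tidy()` returns one row per retained sweep position with summaries of the
#' divergence array; `glance()` a one-row overview.
#'
#' @param x A `pbwt` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pbwt <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    mean_divergence = vapply(x$d, function(d) mean(d), numeric(1)),
    max_match_length = mapply(function(k, d) {
      if (length(d) < 2L) 0L else k - min(d[-1L])
    }, x$k, x$d)
  )
}

#' @rdname tidy.pbwt
#' @export
glance.pbwt <- function(x, ...) {
  tibble::tibble(n_haplotypes = x$M, n_sites = x$N,
                 max_alphabet = if (x$N) max(x$alphabet) else NA_integer_,
                 n_states = length(x$k), keep = x$keep)
}
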