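#' Phased haplotype panel with per-site allele alphabets
#'
#' The canonical container consumed by every other function in the package: an
#' `M x N` integer matrix of allele codes (one haplotype per row, one variant
#' site per column) together with the per-site alphabet sizes `t_k`. Allele
#' codes at site `k` are the integers `0, 1, ..., t_k - 1`; for VCF-derived
#' panels code 0 is the REF allele and code `j` the `j`-th ALT. The alphabet
#' may exceed the observed codes (a declared allele need not be carried by any
#' haplotype in the panel) but can never be smaller.
#'
#' All site coordinates in this package are 0-based and intervals are
#' half-open `[start, end)`, matching the index arithmetic of positional
#' Burrows-Wheeler transform algorithms. Haplotype indices are 0-based as
#' well; `sample_ids` (if present) give row labels in row order.
#'
#' @param alleles Integer matrix (`M x N`) of non-negative allele codes.
#'   A vector is interpreted as a single-haplotype panel (one row).
#' @param alphabet Optional integer vector of length `N` of per-site alphabet
#'   sizes `t_k`. Default: the observed alphabet, `1 + max(column)` per site.
#' @param site_ids Optional character vector of `N` site labels (for example
#'   `"chr1:1234"`).
#' @param sample_ids Optional character vector of `M` haplotype labels.
#'
#' @return An object of class `haplotype_panel`: a list with elements
#'   `alleles`, `alphabet`, `site_ids`, `sample_ids`.
#'
#' @examples
#' p <- haplotype_panel(rbind(c(0L, 1L, 2L),
#'                            c(1L, 1L, 0L),
#'                            c(0L, 1L, 0L),
#'                            c(2L, 0L, 1L)))
#' p
#' panel_alphabet(p)
#' @export
haplotype_panel <- function(alleles, alphabet = NULL, site_ids = NULL,
                            sample_ids = NULL) {
  if (is.vector(alleles)) alleles <- matrix(as.integer(alleles), nrow = 1L)
  if (!is.matrix(alleles)) stop("`alleles` must be a matrix", call. = FALSE)
  storage.mode(alleles) <- "integer"
  M <- nrow(alleles); N <- ncol(alleles)
  if (M < 1L) stop("a haplotype panel needs at least one haplotype (M >= 1)",
                   call. = FALSE)
  if (anyNA(alleles)) stop("allele codes must not be missing", call. = FALSE)
  if (N > 0L && min(alleles) < 0L)
    stop("allele codes must be non-negative integers", call. = FALSE)
  observed <- if (N > 0L) apply(alleles, 2L, max) + 1L else integer(0)
  if (is.null(alphabet)) {
    alphabet <- observed
  } else {
    alphabet <- as.integer(alphabet)
    if (length(alphabet) == 1L) alphabet <- rep(alphabet, N)
    if (length(alphabet) != N)
      stop("`alphabet` must have one entry per site", call. = FALSE)
    bad <- which(alphabet < pmax(observed, 1L))
    if (length(bad))
      stop(sprintf("alphabet size %d at site %d is smaller than 1 + max observed code",
                   alphabet[bad[1]], bad[1] - 1L), call. = FALSE)
  }
  if (!is.null(site_ids) && length(site_ids) != N)
    stop("`site_ids` must have one entry per site", call. = FALSE)
  if (!is.null(sample_ids) && length(sample_ids) != M)
    stop("`sample_ids` must have one entry per haplotype", call. = FALSE)
  structure(list(alleles = alleles, alphabet = alphabet,
                 site_ids = site_ids, sample_ids = sample_ids),
            class = "haplotype_panel")
}

#' @rdname haplotype_panel
#' @param x,object A `haplotype_panel`.
#' @export
is_haplotype_panel <- function(x) inherits(x, "haplotype_panel")

#' @rdname haplotype_panel
#' @export
panel_alphabet <- function(x) {
  stopifnot(is_haplotype_panel(x))
  x$alphabet
}

#' @rdname haplotype_panel
#' @export
dim.haplotype_panel <- function(x) dim(x$alleles)

#' @rdname haplotype_panel
#' @param ... Unused.
#' @exportS3Method base::print
print.haplotype_panel <- function(x, ...) {
  M <- nrow(x$alleles); N <- ncol(x$alleles)
  tmax <- if (N) max(x$alphabet) else NA_integer_
  cat(sprintf("<haplotype_panel> %d haplotypes x %d sites (max alphabet %s)\n",
              M, N, tmax))
  nsh <- min(M, 8L); nsc <- min(N, 20L)
  if (N && M) {
    sub <- x$alleles[seq_len(nsh), seq_len(nsc), drop = FALSE]
    for (i in seq_len(nsh))
      cat(" ", paste(sub[i, ], collapse = " "),
          if (nsc < N) "..." else "", "\n")
    if (nsh < M) cat("  ...\n")
  }
  invisible(x)
}

#' @rdname haplotype_panel
#' @export
glance.haplotype_panel <- function(x, ...) {
  N <- ncol(x$alleles)
  tibble::tibble(
    n_haplotypes = nrow(x$alleles),
    n_sites = N,
    max_alphabet = if (N) max(x$alphabet) else NA_integer_,
    n_multiallelic = sum(x$alphabet > 2L),
    frac_multiallelic = if (N) mean(x$alphabet > 2L) else NA_real_
  )
}

# internal: stop unless a valid panel
assert_panel <- function(panel, arg = "panel") {
  if (!is_haplotype_panel(panel))
    stop(sprintf("`%s` must be a haplotype_panel (see ?haplotype_panel)", arg),
         call. = FALSE)
  invisible(panel)
}
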