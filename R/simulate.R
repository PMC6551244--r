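#' Simulate a haplotype panel with LD-like block structure
#'
#' A self-contained copying-model simulator. The first haplotype draws each
#' site independently with a per-site derived-allele frequency uniform on
#' `base_maf`. Every later haplotype copies blocks from previously generated
#' haplotypes: the template is switched after a geometric number of sites
#' with mean `block_length`, and each copied allele flips with probability
#' `mut_rate`. Copying the same template over runs of adjacent sites is what
#' induces linkage disequilibrium-like correlation between neighboring
#' columns; `block_length = 1` switches the template at every site and
#' removes it. Output is strictly bi-allelic; use [multiallelify()] to
#' convert a fraction of sites to a larger alphabet, as in panels where
#' multi-allelic SNPs or copy-number classes are interspersed with
#' bi-allelic SNPs.
#'
#' @param M Number of haplotypes.
#' @param N Number of sites.
#' @param base_maf Length-2 numeric range for per-site derived-allele
#'   frequencies of the founder haplotype draw.
#' @param block_length Mean copying-block length in sites (`>= 1`).
#' @param mut_rate Per-site copy error (allele flip) probability.
#' @param seed Optional integer seed; the same seed gives an identical panel.
#' @return A bi-allelic [haplotype_panel] (all alphabet sizes 2).
#' @examples
#' p <- simulate_panel(20, 50, seed = 1)
#' glance(p)
#' @export
simulate_panel <- function(M, N, base_maf = c(0.05, 0.5), block_length = 20,
                           mut_rate = 0.01, seed = NULL) {
  M <- as.integer(M); N <- as.integer(N)
  if (M < 1L || N < 0L) stop("need M >= 1 and N >= 0", call. = FALSE)
  if (block_length < 1) stop("`block_length` must be >= 1", call. = FALSE)
  if (mut_rate < 0 || mut_rate > 1)
    stop("`mut_rate` must be in [0, 1]", call. = FALSE)
  if (length(base_maf) != 2L || any(base_maf < 0) || any(base_maf > 1))
    stop("`base_maf` must be a range inside [0, 1]", call. = FALSE)
  gen <- function() {
    X <- matrix(0L, nrow = M, ncol = N)
    if (N > 0L) {
      f <- runif(N, base_maf[1], base_maf[2])
      X[1L, ] <- rbinom(N, 1L, f)
      if (M > 1L) {
        p_switch <- 1 / block_length
        for (i in 2:M) {
          # geometric copying blocks: switch template with prob 1/block_length
          sw <- c(TRUE, runif(N - 1L) < p_switch)
          seg <- cumsum(sw)
          tmpl <- sample.int(i - 1L, max(seg), replace = TRUE)
          v <- X[cbind(tmpl[seg], seq_len(N))]
          flip <- runif(N) < mut_rate
          X[i, ] <- as.integer(ifelse(flip, 1L - v, v))
        }
      }
    }
    haplotype_panel(X, alphabet = rep(2L, N))
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Convert a fraction of sites of a bi-allelic panel to a larger alphabet
#'
#' At a seeded random subset of `ceiling(fraction * N)` sites, the carriers
#' of one of the two alleles (chosen at random per site) are reassigned codes
#' drawn uniformly from `{0, ..., target_t - 1}`, and the site's declared
#' alphabet size becomes `target_t` (a declared allele may end up unobserved).
#' All other sites are untouched.
#'
#' @param panel A strictly bi-allelic [haplotype_panel].
#' @param fraction Fraction of sites to convert, in `[0, 1]`.
#' @param target_t Alphabet size at converted sites (`>= 2`).
#' @param seed Optional integer seed.
#' @return A [haplotype_panel] with `ceiling(fraction * N)` sites of alphabet
#'   size `target_t`.
#' @export
multiallelify <- function(panel, fraction, target_t = 3L, seed = NULL) {
  assert_panel(panel)
  if (fraction < 0 || fraction > 1)
    stop("`fraction` must be in [0, 1]", call. = FALSE)
  target_t <- as.integer(target_t)
  if (target_t < 2L) stop("`target_t` must be >= 2", call. = FALSE)
  if (any(panel$alphabet > 2L))
    stop("`multiallelify()` expects a bi-allelic input panel", call. = FALSE)
  N <- ncol(panel$alleles)
  n_conv <- as.integer(ceiling(fraction * N))
  if (n_conv == 0L) return(panel)
  gen <- function() {
    X <- panel$alleles
    alphabet <- panel$alphabet
    sites <- sort(sample.int(N, n_conv))
    for (k in sites) {
      src <- sample(0:1, 1L)
      carriers <- which(X[, k] == src)
      if (length(carriers))
        X[carriers, k] <- sample.int(target_t, length(carriers),
                                     replace = TRUE) - 1L
      alphabet[k] <- target_t
    }
    haplotype_panel(X, alphabet = alphabet, site_ids = panel$site_ids,
                    sample_ids = panel$sample_ids)
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Uniform random panel with a fixed alphabet
#'
#' Every cell is drawn uniformly from `{0, ..., t - 1}` with no correlation
#' between sites — the adversarial input used by the brute-force validation
#' suite (no LD structure, maximal allele diversity).
#'
#' @param M Number of haplotypes.
#' @param N Number of sites.
#' @param t Alphabet size at every site.
#' @param seed Optional integer seed.
#' @return A [haplotype_panel] with all alphabet sizes `t`.
#' @export
random_panel <- function(M, N, t = 2L, seed = NULL) {
  M <- as.integer(M); N <- as.integer(N); t <- as.integer(t)
  stopifnot(M >= 1L, N >= 0L, t >= 1L)
  gen <- function() {
    X <- matrix(sample.int(t, M * N, replace = TRUE) - 1L, nrow = M)
    haplotype_panel(X, alphabet = rep(t, N))
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Mean adjacent-site linkage disequilibrium (r-squared)
#'
#' Squared Pearson correlation of allele codes between each pair of adjacent
#' columns, averaged over pairs with variation at both sites — the standard
#' r^2 summary of linkage disequilibrium, which is invariant to the arbitrary
#' 0/1 labeling of alleles (signed correlations average to zero because
#' variant clades at different sites may be nested or disjoint). For M
#' haplotypes of independent sites its expectation is about `1 / (M - 1)`,
#' so values well above that indicate LD-like structure.
#'
#' @param panel A [haplotype_panel] (intended for bi-allelic panels).
#' @return A scalar (NA if no adjacent pair varies).
#' @export
adjacent_site_correlation <- function(panel) {
  assert_panel(panel)
  X <- panel$alleles
  N <- ncol(X)
  if (N < 2L) return(NA_real_)
  cors <- vapply(seq_len(N - 1L), function(k) {
    x <- X[, k]; y <- X[, k + 1L]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)^2
  }, numeric(1))
  mean(cors, na.rm = TRUE)
}
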