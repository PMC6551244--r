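#' Read a haplotype panel from a plain allele-matrix file
#'
#' The plain matrix format is one haplotype per line, whitespace-separated
#' non-negative integer allele codes, all lines of equal length. Lines
#' starting with `#` are ignored.
#'
#' @param path Path to the matrix file.
#' @param alphabet_mode `"observed"` (per-site alphabet is `1 + max` observed
#'   code) or `"fixed"` (every site gets alphabet size `t`; a code `>= t` is
#'   an error).
#' @param t Fixed alphabet size, required when `alphabet_mode = "fixed"`.
#' @return A [haplotype_panel].
#' @examples
#' f <- tempfile()
#' writeLines(c("0 1 2", "1 1 0", "0 1 0", "2 0 1"), f)
#' read_panel_matrix(f)
#' @export
read_panel_matrix <- function(path, alphabet_mode = c("observed", "fixed"),
                              t = NULL) {
  alphabet_mode <- match.arg(alphabet_mode)
  if (alphabet_mode == "fixed" && (is.null(t) || t < 1L))
    stop("`t` (>= 1) is required with alphabet_mode = \"fixed\"", call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("'%s': no such file", path), call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    stop(sprintf("'%s': no haplotype rows (M >= 1 required)", path),
         call. = FALSE)
  toks <- strsplit(trimws(lines), "\\s+")
  n0 <- length(toks[[1]])
  for (i in seq_along(toks)) {
    if (length(toks[[i]]) != n0)
      stop(sprintf("'%s' line %d: %d fields, expected %d (ragged rows)",
                   path, lineno[i], length(toks[[i]]), n0), call. = FALSE)
    bad <- !grepl("^[0-9]+$", toks[[i]])
    if (any(bad))
      stop(sprintf("'%s' line %d: token '%s' is not a non-negative integer",
                   path, lineno[i], toks[[i]][which(bad)[1]]), call. = FALSE)
  }
  X <- matrix(as.integer(unlist(toks)), nrow = length(toks), byrow = TRUE)
  if (alphabet_mode == "fixed") {
    over <- which(X >= t, arr.ind = TRUE)
    if (nrow(over))
      stop(sprintf("allele code %d at haplotype %d, site %d violates fixed alphabet t = %d",
                   X[over[1, 1], over[1, 2]], over[1, 1] - 1L, over[1, 2] - 1L,
                   as.integer(t)), call. = FALSE)
    haplotype_panel(X, alphabet = rep(as.integer(t), ncol(X)))
  } else {
    haplotype_panel(X)
  }
}

#' Write a haplotype panel as a plain allele matrix
#'
#' @param panel A [haplotype_panel].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_matrix <- function(panel, path) {
  assert_panel(panel)
  writeLines(apply(panel$alleles, 1L, paste, collapse = " "), path)
  invisible(path)
}

#' Read a phased VCF as a haplotype panel
#'
#' Each diploid sample contributes two haplotype rows, the left allele of the
#' phase separator first. Allele codes are VCF allele indices (0 = REF, `j` =
#' `j`-th ALT), so a site with `a` ALT alleles has alphabet size `a + 1`.
#' Genotypes must be phased (`|` separator); unphased and half-called
#' genotypes are errors. Fully missing genotypes (`.`, `./.`, `.|.`) are
#' governed by `missing_policy`: `"reject"` errors naming the site,
#' `"extra_allele"` codes the missing allele as `t_k`, growing that site's
#' alphabet by one.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param region Optional region filter, `"chrom"` or `"chrom:start-end"`
#'   (1-based, inclusive, on POS).
#' @param missing_policy `"reject"` (default) or `"extra_allele"`.
#' @return A [haplotype_panel] with `site_ids` `"CHROM:POS"` and `sample_ids`
#'   `"<sample>_1"` / `"<sample>_2"`.
#' @export
read_panel_vcf <- function(path, region = NULL,
                           missing_policy = c("reject", "extra_allele")) {
  missing_policy <- match.arg(missing_policy)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  if (!nrow(fix)) stop(sprintf("'%s': no variant records", path), call. = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop(sprintf("'%s': no samples with genotypes", path), call. = FALSE)
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(?::([0-9]+)-([0-9]+))?$", region))[[1]]
    if (!length(m)) stop(sprintf("cannot parse region '%s'", region), call. = FALSE)
    keep <- chrom == m[2]
    if (nzchar(m[3]))
      keep <- keep & pos >= as.integer(m[3]) & pos <= as.integer(m[4])
    if (!any(keep))
      stop(sprintf("region '%s' retains no sites", region), call. = FALSE)
  }
  fix <- fix[keep, , drop = FALSE]; gt <- gt[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]
  alt <- fix[, "ALT"]
  n_alt <- ifelse(is.na(alt) | alt == "." | alt == "", 0L,
                  lengths(strsplit(alt, ",", fixed = TRUE)))
  tk <- n_alt + 1L
  site_ids <- paste0(chrom, ":", pos)
  samples <- colnames(gt)[-1L]
  Nsites <- nrow(gt)
  M <- 2L * length(samples)
  X <- matrix(0L, nrow = M, ncol = Nsites)
  tk_out <- tk
  # GT is the leading colon-separated field of each genotype string
  for (s in seq_along(samples)) {
    gts <- sub(":.*$", "", gt[, s + 1L])
    gts[is.na(gts)] <- "."  # vcfR reads missing genotypes as NA
    fully_missing <- gts %in% c(".", "./.", ".|.")
    halves <- strsplit(gts, "[|]")
    unphased <- !fully_missing & grepl("/", gts, fixed = TRUE)
    if (any(unphased))
      stop(sprintf("unphased genotype '%s' for sample %s at %s",
                   gts[which(unphased)[1]], samples[s],
                   site_ids[which(unphased)[1]]), call. = FALSE)
    nall <- lengths(halves)
    bad_ploidy <- !fully_missing & nall != 2L
    if (any(bad_ploidy))
      stop(sprintf("genotype '%s' for sample %s at %s is not diploid phased",
                   gts[which(bad_ploidy)[1]], samples[s],
                   site_ids[which(bad_ploidy)[1]]), call. = FALSE)
    h1 <- vapply(halves, function(h) h[1], "")
    h2 <- vapply(halves, function(h) if (length(h) > 1L) h[2] else h[1], "")
    half_call <- !fully_missing & xor(h1 == ".", h2 == ".")
    if (any(half_call))
      stop(sprintf("half-called genotype '%s' for sample %s at %s",
                   gts[which(half_call)[1]], samples[s],
                   site_ids[which(half_call)[1]]), call. = FALSE)
    miss <- fully_missing | (h1 == "." & h2 == ".")
    if (any(miss) && missing_policy == "reject")
      stop(sprintf("missing genotype for sample %s at %s (missing_policy = \"reject\")",
                   samples[s], site_ids[which(miss)[1]]), call. = FALSE)
    c1 <- suppressWarnings(as.integer(h1))
    c2 <- suppressWarnings(as.integer(h2))
    c1[miss] <- NA_integer_; c2[miss] <- NA_integer_
    bad <- !miss & (is.na(c1) | is.na(c2) | c1 >= tk | c2 >= tk | c1 < 0L | c2 < 0L)
    if (any(bad))
      stop(sprintf("genotype '%s' for sample %s at %s has an allele outside [0, %d)",
                   gts[which(bad)[1]], samples[s], site_ids[which(bad)[1]],
                   tk[which(bad)[1]]), call. = FALSE)
    if (any(miss)) {
      # extra_allele: '.' becomes code t_k at that site
      c1[miss] <- tk[miss]; c2[miss] <- tk[miss]
      tk_out[miss] <- pmax(tk_out[miss], tk[miss] + 1L)
    }
    X[2L * s - 1L, ] <- c1
    X[2L * s, ] <- c2
  }
  haplotype_panel(X, alphabet = tk_out, site_ids = site_ids,
                  sample_ids = as.vector(rbind(paste0(samples, "_1"),
                                               paste0(samples, "_2"))))
}

#' Read a haplotype panel, auto-detecting the format
#'
#' @param path Input path.
#' @param format `"auto"` (by extension: `.vcf`/`.vcf.gz` is VCF, anything
#'   else plain matrix), `"vcf"` or `"matrix"`.
#' @param ... Passed to [read_panel_vcf()] or [read_panel_matrix()].
#' @return A [haplotype_panel].
#' @export
read_panel <- function(path, format = c("auto", "vcf", "matrix"), ...) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "matrix"
  switch(format,
         vcf = read_panel_vcf(path, ...),
         matrix = read_panel_matrix(path, ...))
}

#' Write match records to a TSV report
#'
#' Writes the header line `#hap_i hap_j start end length` followed by one
#' tab-separated line per record. Records are sorted by `end`, then `start`,
#' then `hap_i`, then `hap_j`, so the report is deterministic.
#'
#' @param matches A data frame of match records with columns `hap_i`, `hap_j`,
#'   `start`, `end` (as returned by [find_long_matches()] or
#'   [set_maximal_matches()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  stopifnot(is.data.frame(matches),
            all(c("hap_i", "hap_j", "start", "end") %in% names(matches)))
  m <- matches[order(matches$end, matches$start, matches$hap_i, matches$hap_j), ,
               drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#hap_i\thap_j\tstart\tend\tlength", con)
  if (nrow(m))
    writeLines(sprintf("%d\t%d\t%d\t%d\t%d", m$hap_i, m$hap_j, m$start, m$end,
                       m$end - m$start), con)
  invisible(path)
}

#' Read a match report written by [write_matches()]
#'
#' @param path Path to the TSV report.
#' @return A tibble with columns `hap_i`, `hap_j`, `start`, `end`, `length`.
#' @export
read_matches <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(tibble::tibble(hap_i = integer(), hap_j = integer(),
                          start = integer(), end = integer(),
                          length = integer()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  m <- matrix(as.integer(unlist(f)), ncol = 5L, byrow = TRUE)
  tibble::tibble(hap_i = m[, 1], hap_j = m[, 2], start = m[, 3], end = m[, 4],
                 length = m[, 5])
}
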