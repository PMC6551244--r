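# Shared fixtures and comparison helpers, all built in code.

# the 4 x 3 tri-allelic panel used as the worked example throughout
worked_panel <- function() {
  haplotype_panel(rbind(c(0L, 1L, 2L),
                        c(1L, 1L, 0L),
                        c(0L, 1L, 0L),
                        c(2L, 0L, 1L)))
}

# strip class/attrs and impose canonical row order so two match tables can be
# compared by content
match_df <- function(x) {
  d <- as.data.frame(x)[, c("hap_i", "hap_j", "start", "end", "length")]
  d <- d[order(d$end, d$start, d$hap_i, d$hap_j), , drop = FALSE]
  rownames(d) <- NULL
  d
}

expect_same_matches <- function(actual, expected) {
  expect_equal(match_df(actual), match_df(expected))
}

# every record must agree on its interval and mismatch (or hit the panel
# boundary) at both ends; aggregated into one expectation per call
matches_sound <- function(panel, records) {
  X <- panel$alleles
  N <- ncol(X)
  for (r in seq_len(nrow(records))) {
    i <- records$hap_i[r] + 1L; j <- records$hap_j[r] + 1L
    s <- records$start[r]; e <- records$end[r]
    if (!(s >= 0L && s < e && e <= N)) return(FALSE)
    if (!all(X[i, (s + 1L):e] == X[j, (s + 1L):e])) return(FALSE)
    if (s > 0L && X[i, s] == X[j, s]) return(FALSE)
    if (e < N && X[i, e + 1L] == X[j, e + 1L]) return(FALSE)
  }
  TRUE
}

expect_matches_sound <- function(panel, records) {
  expect_true(matches_sound(panel, records))
}

# write a small phased VCF from genotype rows; gt is a matrix of GT strings
# (sites x samples)
write_vcf_fixture <- function(ref, alt, gt, chrom = "1",
                              pos = seq_len(length(ref)) * 100L,
                              path = tempfile(fileext = ".vcf")) {
  samples <- paste0("S", seq_len(ncol(gt)))
  header <- c("##fileformat=VCFv4.2",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(ref), function(k) {
    paste(c(chrom, pos[k], ".", ref[k], alt[k], ".", ".", ".", "GT",
            gt[k, ]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}

# the seeded panel family shared by the oracle-equivalence checks: dimensions
# and alphabet drawn per replicate, uniform random alleles
validation_panel <- function(r) {
  withr::with_seed(1000L + r, {
    M <- sample(2:30, 1)
    N <- sample(1:60, 1)
    t <- sample(c(2L, 3L, 5L, 10L), 1)
    L <- sample.int(N, 1)
    list(panel = random_panel(M, N, t), L = L, M = M, N = N, t = t)
  })
}
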