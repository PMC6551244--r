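test_that("worked panel yields its two long matches of length >= 2", {
  p <- worked_panel()
  m <- find_long_matches(p, 2)
  expect_equal(match_df(m),
               data.frame(hap_i = c(0L, 1L), hap_j = c(2L, 2L),
                          start = c(0L, 1L), end = c(2L, 3L),
                          length = c(2L, 2L)))
  expect_matches_sound(p, m)
})

test_that("interior block scan reports only mismatch-terminated pairs", {
  p <- worked_panel()
  b <- pbwt_build(p)
  st <- pbwt_state(b, 2)
  m <- long_matches_at(st, p$alleles[, 3], L = 2)
  expect_equal(nrow(m), 1L)
  expect_equal(match_df(m),
               data.frame(hap_i = 0L, hap_j = 2L, start = 0L, end = 2L,
                          length = 2L))
  # no mismatch at k -> nothing terminates
  ident <- haplotype_panel(matrix(0L, 3, 4), alphabet = rep(2L, 4))
  bi <- pbwt_build(ident)
  expect_equal(nrow(long_matches_at(pbwt_state(bi, 2), ident$alleles[, 3], 2)),
               0L)
  # M = 2, L > k: block cannot be long enough
  p2 <- haplotype_panel(rbind(c(0L, 0L, 1L), c(0L, 0L, 0L)),
                        alphabet = rep(2L, 3))
  b2 <- pbwt_build(p2)
  expect_equal(nrow(long_matches_at(pbwt_state(b2, 2), p2$alleles[, 3], 3)),
               0L)
  expect_error(long_matches_at(st, p$alleles[, 3], 0), "positive")
})

test_that("last-site routine reports end-of-panel and just-finished matches", {
  p <- worked_panel()
  b <- pbwt_build(p)
  st <- pbwt_state(b, 2)
  m <- long_matches_last(st, p$alleles[, 3], L = 2, N = 3)
  expect_equal(match_df(m),
               data.frame(hap_i = c(0L, 2L), hap_j = c(2L, 1L),
                          start = c(0L, 1L), end = c(2L, 3L),
                          length = c(2L, 2L)))
  # identical pair reaches end = N for any L <= N
  q <- haplotype_panel(rbind(rep(0L, 4), rep(0L, 4)), alphabet = rep(2L, 4))
  bq <- pbwt_build(q)
  mq <- long_matches_last(pbwt_state(bq, 3), q$alleles[, 4], L = 4, N = 4)
  expect_equal(match_df(mq),
               data.frame(hap_i = 0L, hap_j = 1L, start = 0L, end = 4L,
                          length = 4L))
  # sharing exactly L - 1 trailing sites is below threshold
  r <- haplotype_panel(rbind(c(0L, 1L, 0L, 0L), c(1L, 0L, 0L, 0L)),
                       alphabet = rep(2L, 4))
  br <- pbwt_build(r)
  expect_equal(nrow(long_matches_last(pbwt_state(br, 3), r$alleles[, 4],
                                      L = 3, N = 4)), 0L)
  expect_error(long_matches_last(pbwt_state(br, 3), r$alleles[, 4], 3, 5),
               "last site")
})

test_that("long matches equal the all-pairs oracle on random panels", {
  for (r in 1:40) {
    cfg <- validation_panel(r)
    m <- find_long_matches(cfg$panel, cfg$L)
    expect_same_matches(m, oracle_matches(cfg$panel, cfg$L))
    expect_matches_sound(cfg$panel, m)
    # no duplicate pair-intervals
    expect_equal(anyDuplicated(m[c("hap_i", "hap_j", "start", "end")]), 0L)
  }
})

test_that("L = N with all haplotypes distinct yields no matches", {
  p <- haplotype_panel(rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L)),
                       alphabet = rep(2L, 2))
  expect_equal(nrow(find_long_matches(p, 2)), 0L)
})

test_that("fully identical haplotype pairs are reported over the whole panel", {
  base <- random_panel(6, 12, 3, seed = 21)
  X <- rbind(base$alleles, base$alleles[2, ], base$alleles[5, ])
  p <- haplotype_panel(X, alphabet = panel_alphabet(base))
  m <- find_long_matches(p, 12)
  expect_true(all(c(paste(1, 6), paste(4, 7)) %in%
                    paste(m$hap_i, m$hap_j)))
  full <- m[m$start == 0L & m$end == 12L, ]
  expect_true(nrow(full) >= 2L)
  sm <- set_maximal_matches(p)
  expect_true(any(sm$hap_i == 1L & sm$hap_j == 6L & sm$start == 0L &
                    sm$end == 12L))
})

test_that("set-maximal matches on the worked panel are per query", {
  p <- worked_panel()
  sm <- set_maximal_matches(p)
  expect_equal(match_df(sm),
               data.frame(hap_i = c(0L, 2L, 1L, 2L), hap_j = c(2L, 0L, 2L, 1L),
                          start = c(0L, 0L, 1L, 1L), end = c(2L, 2L, 3L, 3L),
                          length = c(2L, 2L, 2L, 2L))[c(1, 2, 3, 4), ])
  # haplotype 3 has no nonzero-length match to any sequence
  expect_false(any(sm$hap_i == 3L))
  expect_error(set_maximal_matches(haplotype_panel(rbind(c(0L, 1L)))),
               "two haplotypes")
})

test_that("identical panels give full-length neighbor matches for every query", {
  p <- haplotype_panel(matrix(2L, 4, 5), alphabet = rep(3L, 5))
  sm <- set_maximal_matches(p)
  expect_true(all(sm$start == 0L & sm$end == 5L))
  expect_true(all(0:3 %in% sm$hap_i))
})

test_that("set-maximal matches equal the exhaustive oracle on random panels", {
  for (r in 1:40) {
    cfg <- validation_panel(r)
    sm <- set_maximal_matches(cfg$panel)
    expect_same_matches(sm, oracle_set_maximal(cfg$panel))
  }
})

test_that("bi-allelic matching reduces to the classical implementation", {
  for (r in 1:10) {
    p <- withr::with_seed(100 + r,
                          random_panel(sample(2:15, 1), sample(2:25, 1), 2))
    L <- withr::with_seed(200 + r, sample.int(ncol(p$alleles), 1))
    expect_same_matches(find_long_matches(p, L), durbin_long_matches(p, L))
    expect_same_matches(set_maximal_matches(p), durbin_set_maximal(p))
  }
})

test_that("canonicalization orders pairs and drops duplicates", {
  m <- tibble::tibble(hap_i = c(2L, 0L), hap_j = c(0L, 2L),
                      start = c(0L, 0L), end = c(2L, 2L))
  cm <- canonicalize_matches(m)
  expect_equal(nrow(cm), 1L)
  expect_equal(cm$hap_i, 0L)
  expect_equal(cm$hap_j, 2L)
})
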