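test_that("transform permutes each column into reversed-prefix order", {
  p <- worked_panel()
  tp <- pbwt_transform(p)
  expect_equal(tp$y[, 1], c(0L, 1L, 0L, 2L))
  # y_1 is column 1 gathered through a_1 = [0, 2, 1, 3]
  expect_equal(tp$y[, 2], p$alleles[c(0L, 2L, 1L, 3L) + 1L, 2])
  b <- pbwt_build(p)
  for (k in 1:3) {
    expect_equal(tp$y[, k], p$alleles[pbwt_state(b, k - 1)$a + 1L, k])
  }
  expect_equal(tp$c[[1]], c(2L, 1L, 1L))
  # counts sum to M at every site
  expect_true(all(vapply(tp$c, sum, integer(1)) == 4L))
})

test_that("identical rows transform to constant columns and single runs", {
  p <- haplotype_panel(matrix(1L, 6, 4), alphabet = rep(2L, 4))
  tp <- pbwt_transform(p)
  expect_true(all(tp$y == 1L))
  expect_equal(mpbwt:::rle_vals(tp$y[, 1]), c(1, 1, 6))
})

test_that("extension function satisfies its fixed points and inverse law", {
  p <- worked_panel()
  tp <- pbwt_transform(p)
  expect_equal(extend_rank(tp, 0, 1, 1), 2L)
  b <- pbwt_build(p)
  for (k in 0:2) {
    t_k <- panel_alphabet(p)[k + 1]
    expect_equal(extend_rank(tp, k, 0, 0), 0L)
    expect_equal(extend_rank(tp, k, 4, t_k - 1L), 4L)
    a_k <- pbwt_state(b, k)$a
    a_k1 <- pbwt_state(b, k + 1)$a
    for (i in 0:3) {
      w <- extend_rank(tp, k, i, tp$y[i + 1, k + 1])
      expect_equal(a_k1[w + 1], a_k[i + 1])
    }
  }
  expect_error(extend_rank(tp, 0, 1, 3), "outside alphabet")
})

test_that("extension inverse holds exhaustively on random panels", {
  for (r in 1:6) {
    p <- withr::with_seed(300 + r,
                          random_panel(sample(2:12, 1), sample(1:12, 1),
                                       sample(c(2L, 3L, 5L), 1)))
    M <- nrow(p$alleles); N <- ncol(p$alleles)
    tp <- pbwt_transform(p, checkpoint_stride = 5, occ_stride = 3)
    b <- pbwt_build(p)
    for (k in 0:(N - 1)) {
      a_k <- pbwt_state(b, k)$a
      a_k1 <- pbwt_state(b, k + 1)$a
      for (i in seq_len(M) - 1L) {
        w <- extend_rank(tp, k, i, tp$y[i + 1, k + 1])
        expect_identical(a_k1[w + 1], a_k[i + 1])
      }
    }
  }
})

test_that("container encoding is deterministic and self-describing", {
  p <- random_panel(9, 17, 4, seed = 31)
  tp <- pbwt_transform(p, checkpoint_stride = 4, occ_stride = 4)
  b1 <- pbwt_encode(tp)
  b2 <- pbwt_encode(pbwt_transform(p, checkpoint_stride = 4, occ_stride = 4))
  expect_identical(b1, b2)
  expect_identical(b1[1:5], charToRaw("MPBWT"))
  tp2 <- pbwt_decode(b1)
  expect_equal(tp2$y, tp$y)
  expect_equal(tp2$c, tp$c)
  expect_equal(tp2$occ, tp$occ)
  expect_equal(tp2$cp_sites, tp$cp_sites)
  expect_equal(tp2$cp_a, lapply(tp$cp_a, as.integer))
})

test_that("corrupt containers are rejected with format errors", {
  tp <- pbwt_transform(worked_panel())
  bytes <- pbwt_encode(tp)
  bad <- bytes; bad[2] <- as.raw(88)
  expect_error(pbwt_decode(bad), "bad magic")
  vbad <- bytes; vbad[6] <- as.raw(99)
  expect_error(pbwt_decode(vbad), "version 99.*version 1")
  expect_error(pbwt_decode(bytes[1:(length(bytes) - 4)]), "truncated|corrupt")
  expect_error(pbwt_decode(raw(3)), "too short")
})

test_that("transform -> encode -> decode -> reconstruct is the identity", {
  p <- worked_panel()
  expect_identical(pbwt_reconstruct(pbwt_decode(pbwt_encode(pbwt_transform(p))))$alleles,
                   p$alleles)
  for (r in 1:20) {
    q <- withr::with_seed(400 + r,
                          random_panel(sample(2:50, 1), sample(1:100, 1),
                                       sample(c(2L, 3L, 10L), 1)))
    rt <- pbwt_reconstruct(pbwt_decode(pbwt_encode(pbwt_transform(q))))
    expect_identical(rt$alleles, q$alleles)
    expect_identical(panel_alphabet(rt), panel_alphabet(q))
  }
  # single haplotype and zero-site panels round-trip trivially
  one <- random_panel(1, 7, 3, seed = 5)
  expect_identical(pbwt_reconstruct(pbwt_decode(pbwt_encode(pbwt_transform(one))))$alleles,
                   one$alleles)
  empty <- haplotype_panel(matrix(integer(0), 3, 0))
  expect_equal(dim(pbwt_reconstruct(pbwt_transform(empty))), c(3L, 0L))
})

test_that("bi-allelic transform agrees with the classical y arrays", {
  for (r in 1:8) {
    p <- withr::with_seed(500 + r,
                          random_panel(sample(2:15, 1), sample(1:20, 1), 2))
    expect_identical(pbwt_transform(p)$y, durbin_y(p))
  }
})

test_that("file-level compress and decompress round-trip a panel", {
  p <- random_panel(12, 30, 3, seed = 77)
  f <- tempfile(fileext = ".mpbwt")
  compress_panel(p, f)
  q <- decompress_panel(f)
  expect_identical(q$alleles, p$alleles)
})

test_that("reversed-prefix order improves run-length size under LD", {
  p <- simulate_panel(100, 300, block_length = 25, mut_rate = 0.02, seed = 8)
  tp <- pbwt_transform(p)
  expect_lt(rle_column_bytes(tp$y), rle_column_bytes(p$alleles))
})
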