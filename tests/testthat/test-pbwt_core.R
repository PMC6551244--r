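# Frozen expected values below were computed with oracle_sort (explicit
# reversed-prefix sort + longest-common-suffix divergence) on the worked
# panel and verified before being frozen.

test_that("one sweep step performs a stable counting sort with divergences", {
  st <- pbwt_init_state(4)
  s1 <- pbwt_advance(st, c(0L, 1L, 0L, 2L), t_k = 3)
  expect_equal(s1$a, c(0L, 2L, 1L, 3L))
  expect_equal(s1$d, c(1L, 0L, 1L, 1L))
  # second step of the worked panel (column 1 per haplotype: 1,1,1,0)
  s2 <- pbwt_advance(s1, c(1L, 1L, 1L, 0L), t_k = 2)
  expect_equal(s2$a, c(3L, 0L, 2L, 1L))
  expect_equal(s2$d, c(2L, 2L, 0L, 1L))
})

test_that("a constant column is a single bucket and preserves everything", {
  st <- list(k = 5L, a = c(3L, 0L, 2L, 1L), d = c(5L, 2L, 0L, 4L))
  s <- pbwt_advance(st, rep(1L, 4), t_k = 3)
  expect_equal(s$a, st$a)
  # all matches extend: interior divergences unchanged, sentinel moves to k+1
  expect_equal(s$d, c(6L, 2L, 0L, 4L))
})

test_that("prefix-only advance matches the full step and M = 1 is trivial", {
  st <- pbwt_init_state(4)
  s <- pbwt_advance(st, c(0L, 1L, 0L, 2L), t_k = 3, divergence = FALSE)
  expect_equal(s$a, c(0L, 2L, 1L, 3L))
  expect_null(s$d)
  one <- pbwt_advance(pbwt_init_state(1), 2L, t_k = 3)
  expect_equal(one$a, 0L)
})

test_that("alphabet violations are reported with the site", {
  st <- pbwt_init_state(2)
  expect_error(pbwt_advance(st, c(0L, 2L), t_k = 2), "outside alphabet")
  p <- haplotype_panel(rbind(0:2, c(0L, 0L, 0L)), alphabet = c(3L, 3L, 3L))
  p$alleles[1, 2] <- 9L  # corrupt after construction
  expect_error(pbwt_build(p), "site 1")
})

test_that("build on the worked panel reproduces the oracle at every k", {
  p <- worked_panel()
  b <- pbwt_build(p)
  expect_equal(b$k, 0:3)
  for (k in 0:3) {
    st <- pbwt_state(b, k)
    o <- oracle_sort(p, k)
    expect_equal(st$a, o$a)
    expect_equal(st$d, o$d)
  }
  s3 <- pbwt_state(b, 3)
  expect_equal(s3$a, c(2L, 1L, 3L, 0L))
  expect_equal(s3$d, c(3L, 1L, 3L, 3L))
})

test_that("identical haplotypes never sort and diverge only at the sentinel", {
  p <- haplotype_panel(matrix(1L, nrow = 5, ncol = 6), alphabet = rep(2L, 6))
  b <- pbwt_build(p)
  for (k in 0:6) {
    st <- pbwt_state(b, k)
    expect_equal(st$a, 0:4)
    expect_equal(st$d, c(k, rep(0L, 4)))
  }
})

test_that("keep policies retain the advertised states", {
  p <- random_panel(6, 70, 3, seed = 11)
  ball <- pbwt_build(p, keep = "all")
  expect_equal(ball$k, 0:70)
  bcp <- pbwt_build(p, keep = "checkpoints", stride = 32)
  expect_equal(bcp$k, c(0L, 32L, 64L, 70L))
  bfin <- pbwt_build(p, keep = "final")
  expect_equal(bfin$k, 70L)
  expect_equal(pbwt_state(bfin, 70), pbwt_state(ball, 70))
  expect_error(pbwt_state(bfin, 3), "not retained")
  # zero-site panel: only the initial state
  b0 <- pbwt_build(haplotype_panel(matrix(integer(0), 2, 0)))
  expect_equal(b0$k, 0L)
  expect_equal(pbwt_state(b0, 0)$a, c(0L, 1L))
})

test_that("prefix and divergence arrays equal the brute-force oracle on random panels", {
  for (r in 1:25) {
    cfg <- validation_panel(r)
    b <- pbwt_build(cfg$panel)
    for (k in 0:cfg$N) {
      st <- pbwt_state(b, k)
      o <- oracle_sort(cfg$panel, k)
      expect_identical(st$a, o$a)
      expect_identical(st$d, o$d)
      # permutation invariant
      expect_setequal(st$a, 0:(cfg$M - 1))
    }
  }
})

test_that("reversed prefixes are non-decreasing along every prefix array", {
  for (r in 1:8) {
    cfg <- validation_panel(r)
    X <- cfg$panel$alleles
    b <- pbwt_build(cfg$panel)
    for (k in 0:cfg$N) {
      a <- pbwt_state(b, k)$a
      if (k == 0 || cfg$M == 1) next
      keys <- vapply(a, function(h) {
        paste(sprintf("%02d", rev(X[h + 1L, seq_len(k)])), collapse = "")
      }, "")
      expect_true(!is.unsorted(keys))
    }
  }
})

test_that("bi-allelic panels reduce to the classical two-bucket sweep", {
  for (r in 1:10) {
    p <- withr::with_seed(r, random_panel(sample(2:15, 1), sample(1:25, 1), 2))
    db <- durbin_build(p)
    b <- pbwt_build(p)
    N <- ncol(p$alleles)
    for (k in 0:N) {
      st <- pbwt_state(b, k)
      expect_identical(st$a, db$a[[k + 1]])
      expect_identical(st$d, db$d[[k + 1]])
    }
  }
})

test_that("tidy and glance summarize a pbwt object", {
  b <- pbwt_build(worked_panel())
  td <- tidy(b)
  expect_equal(nrow(td), 4L)
  expect_equal(td$k, 0:3)
  g <- glance(b)
  expect_equal(g$n_haplotypes, 4L)
  expect_equal(g$n_states, 4L)
})
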