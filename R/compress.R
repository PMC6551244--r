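# --- varint (LEB128) codec -------------------------------------------------
# Little-endian base-128 with continuation bit; values are non-negative and
# below 2^31. Both directions are vectorized.

varint_encode <- function(v) {
  v <- as.double(v)
  if (length(v) == 0L) return(raw(0))
  if (any(is.na(v)) || any(v < 0) || any(v >= 2^31))
    stop("varint values must be in [0, 2^31)", call. = FALSE)
  d <- matrix(0, 5L, length(v))
  x <- v
  for (r in 1:5) { d[r, ] <- x %% 128; x <- x %/% 128 }
  nb <- 1L + (v >= 128) + (v >= 128^2) + (v >= 128^3) + (v >= 128^4)
  row_idx <- sequence(nb)
  col_idx <- rep(seq_along(v), nb)
  bytes <- d[cbind(row_idx, col_idx)] + 128 * (row_idx < nb[col_idx])
  as.raw(bytes)
}

# decode every varint in `bytes`; error on a dangling continuation bit
varint_decode_all <- function(bytes) {
  if (length(bytes) == 0L) return(numeric(0))
  b <- as.integer(bytes)
  cont <- b >= 128L
  ends <- which(!cont)
  if (!length(ends) || ends[length(ends)] != length(b))
    stop("truncated container: dangling varint continuation", call. = FALSE)
  starts <- c(1L, ends[-length(ends)] + 1L)
  lens <- ends - starts + 1L
  if (any(lens > 5L)) stop("corrupt container: varint too long", call. = FALSE)
  grp <- rep(seq_along(ends), lens)
  pos <- sequence(lens)
  vals <- (b %% 128L) * 128^(pos - 1)
  as.vector(rowsum(vals, grp))
}

# run-length encode one integer vector -> numeric vector c(nruns, v1, l1, ...)
rle_vals <- function(x) {
  r <- rle(as.integer(x))
  c(length(r$values), as.vector(rbind(r$values, r$lengths)))
}

# total varint bytes of per-column run-length encoding of an integer matrix;
# the codec used for y columns in the container, applied standalone so raw
# and transformed orders can be compared like for like
#' Run-length encoded size of a matrix, column by column
#'
#' Applies the container's run-length + varint codec to each column of an
#' integer matrix and returns the total byte count. Useful for measuring how
#' much the reversed-prefix reordering improves run-length compressibility.
#'
#' @param x Integer matrix (haplotypes by sites).
#' @return Number of bytes.
#' @export
rle_column_bytes <- function(x) {
  stopifnot(is.matrix(x))
  tot <- 0L
  for (k in seq_len(ncol(x)))
    tot <- tot + length(varint_encode(rle_vals(x[, k])))
  tot
}

# --- transform --------------------------------------------------------------

#' Positional FM-index transform of a haplotype panel
#'
#' Produces, for each site `k`, the array `y_k` (the panel column at `k`
#' permuted into reversed-prefix sorted order, `y_k[i] = x[a_k[i]][k]`), the
#' per-allele counts `c_k`, occurrence checkpoints for rank queries, and
#' prefix-array checkpoints every `checkpoint_stride` sites. Together these
#' allow exact reconstruction of the panel ([pbwt_reconstruct()]) and form
#' the content of the run-length encoded container ([pbwt_encode()]).
#'
#' Occurrence counts are checkpointed every `occ_stride` sorted positions
#' (positions `0, B, 2B, ..., <= M`); ranks between checkpoints are recovered
#' by scanning `y_k`, the standard FM-index trade-off between storage and
#' query time.
#'
#' @param panel A [haplotype_panel].
#' @param checkpoint_stride Site stride for stored prefix arrays (default 32).
#' @param occ_stride Sorted-position stride for occurrence checkpoints
#'   (default 64).
#' @return An object of class `mpbwt_transformed`.
#' @examples
#' p <- haplotype_panel(rbind(c(0L, 1L, 2L),
#'                            c(1L, 1L, 0L),
#'                            c(0L, 1L, 0L),
#'                            c(2L, 0L, 1L)))
#' tp <- pbwt_transform(p)
#' tp$y
#' @export
pbwt_transform <- function(panel, checkpoint_stride = 32L, occ_stride = 64L) {
  assert_panel(panel)
  checkpoint_stride <- as.integer(checkpoint_stride)
  occ_stride <- as.integer(occ_stride)
  if (checkpoint_stride < 1L || occ_stride < 1L)
    stop("strides must be positive integers", call. = FALSE)
  M <- nrow(panel$alleles); N <- ncol(panel$alleles)
  res <- mpbwt_transform_cpp(panel$alleles, panel$alphabet, checkpoint_stride)
  cp_pos <- seq.int(0L, M, by = occ_stride)
  occ <- vector("list", N)
  for (k in seq_len(N)) {
    yk <- res$y[, k]
    tk <- panel$alphabet[k]
    oc <- matrix(0L, nrow = tk, ncol = length(cp_pos))
    for (l in seq_len(tk) - 1L) {
      cs <- cumsum(yk == l)
      oc[l + 1L, ] <- c(0L, cs[cp_pos[-1L]])
    }
    occ[[k]] <- oc
  }
  structure(list(y = res$y, c = res$c, occ = occ, occ_stride = occ_stride,
                 occ_positions = cp_pos,
                 cp_sites = res$cp_sites, cp_a = res$cp_a,
                 checkpoint_stride = checkpoint_stride,
                 M = M, N = N, alphabet = panel$alphabet),
            class = "mpbwt_transformed")
}

#' @exportS3Method base::print
print.mpbwt_transformed <- function(x, ...) {
  cat(sprintf("<mpbwt_transformed> %d haplotypes x %d sites; %d prefix-array checkpoint(s), occ stride %d\n",
              x$M, x$N, length(x$cp_sites), x$occ_stride))
  invisible(x)
}

#' The extension (rank) function of the positional FM-index
#'
#' `w_k(i, l) = Occ_k[l][i] + CC_k(l - 1)`, where `Occ_k[l][i]` counts
#' occurrences of allele `l` among `y_k[0..i-1]` and `CC_k` is the cumulative
#' allele count (`CC_k(-1) = 0`). It maps sorted position `i` at site `k` to
#' the sorted position at `k + 1` of the same haplotype when its allele at
#' `k` is `l`: `a_{k+1}[w_k(i, y_k[i])] = a_k[i]`. Ranks are answered from
#' the nearest occurrence checkpoint plus a scan of `y_k`.
#'
#' @param tp An `mpbwt_transformed` object from [pbwt_transform()].
#' @param k Site index, 0-based.
#' @param i Sorted position, `0 <= i <= M`.
#' @param l Allele code, `0 <= l < t_k`.
#' @return The sorted position at `k + 1` (0-based scalar integer).
#' @export
extend_rank <- function(tp, k, i, l) {
  stopifnot(inherits(tp, "mpbwt_transformed"))
  k <- as.integer(k); i <- as.integer(i); l <- as.integer(l)
  if (k < 0L || k >= tp$N) stop("`k` out of range", call. = FALSE)
  if (i < 0L || i > tp$M) stop("`i` must be in [0, M]", call. = FALSE)
  tk <- tp$alphabet[k + 1L]
  if (l < 0L || l >= tk)
    stop(sprintf("allele %d outside alphabet [0, %d) at site %d", l, tk, k),
         call. = FALSE)
  B <- tp$occ_stride
  cp <- i %/% B
  occ <- tp$occ[[k + 1L]][l + 1L, cp + 1L]
  lo <- cp * B
  if (i > lo) occ <- occ + sum(tp$y[(lo + 1L):i, k + 1L] == l)
  cc_prev <- if (l == 0L) 0L else sum(tp$c[[k + 1L]][seq_len(l)])
  as.integer(occ + cc_prev)
}

# --- container --------------------------------------------------------------

MPBWT_MAGIC <- charToRaw("MPBWT")
MPBWT_VERSION <- 1L

#' Serialize a transformed panel to the .mpbwt container
#'
#' A self-describing little-endian binary container: the magic bytes
#' `"MPBWT"` and a version byte, then a varint stream holding the header
#' (`M`, `N`, strides, alphabet sizes), the run-length encoded `y` columns,
#' the per-site allele counts (the last allele's count is omitted and
#' recovered as `M` minus the rest), the occurrence checkpoints, and the
#' prefix-array checkpoints. Byte-for-byte deterministic for a given input.
#'
#' @param tp An `mpbwt_transformed` object.
#' @return A raw vector.
#' @export
pbwt_encode <- function(tp) {
  stopifnot(inherits(tp, "mpbwt_transformed"))
  vals <- vector("list", 6L + 3L * tp$N + length(tp$cp_sites))
  vals[[1]] <- c(tp$M, tp$N, tp$occ_stride, tp$checkpoint_stride,
                 length(tp$cp_sites))
  vals[[2]] <- tp$alphabet
  vi <- 3L
  for (k in seq_len(tp$N)) {
    vals[[vi]] <- rle_vals(tp$y[, k]); vi <- vi + 1L
  }
  for (k in seq_len(tp$N)) {
    ck <- tp$c[[k]]
    vals[[vi]] <- if (length(ck) > 1L) ck[-length(ck)] else numeric(0)
    vi <- vi + 1L
  }
  for (k in seq_len(tp$N)) {
    vals[[vi]] <- as.vector(tp$occ[[k]]); vi <- vi + 1L
  }
  for (j in seq_along(tp$cp_sites)) {
    vals[[vi]] <- c(tp$cp_sites[j], tp$cp_a[[j]]); vi <- vi + 1L
  }
  c(MPBWT_MAGIC, as.raw(MPBWT_VERSION),
    varint_encode(unlist(vals[seq_len(vi - 1L)], use.names = FALSE)))
}

# sequential consumer over a decoded varint value stream
value_reader <- function(vals) {
  pos <- 0L
  function(n) {
    if (pos + n > length(vals))
      stop("truncated container: value stream exhausted", call. = FALSE)
    out <- vals[pos + seq_len(n)]
    pos <<- pos + as.integer(n)
    out
  }
}

#' Deserialize a .mpbwt container
#'
#' Exact inverse of [pbwt_encode()]. Checks the magic bytes and version and
#' fails with a format error on truncated or corrupt input.
#'
#' @param bytes Raw vector produced by [pbwt_encode()].
#' @return An `mpbwt_transformed` object.
#' @export
pbwt_decode <- function(bytes) {
  if (!is.raw(bytes) || length(bytes) < 6L)
    stop("not an mpbwt container (too short)", call. = FALSE)
  if (!identical(bytes[1:5], MPBWT_MAGIC))
    stop("not an mpbwt container (bad magic)", call. = FALSE)
  ver <- as.integer(bytes[6])
  if (ver != MPBWT_VERSION)
    stop(sprintf("container version %d, this build reads version %d",
                 ver, MPBWT_VERSION), call. = FALSE)
  vals <- varint_decode_all(bytes[-(1:6)])
  rd <- value_reader(vals)
  hdr <- rd(5L)
  M <- as.integer(hdr[1]); N <- as.integer(hdr[2])
  occ_stride <- as.integer(hdr[3]); cp_stride <- as.integer(hdr[4])
  n_cp <- as.integer(hdr[5])
  alphabet <- as.integer(rd(N))
  y <- matrix(0L, nrow = M, ncol = N)
  for (k in seq_len(N)) {
    nr <- as.integer(rd(1L))
    runs <- matrix(as.integer(rd(2L * nr)), nrow = 2L)
    col <- rep.int(runs[1L, ], runs[2L, ])
    if (length(col) != M)
      stop(sprintf("corrupt container: runs at site %d sum to %d, expected %d",
                   k - 1L, length(col), M), call. = FALSE)
    y[, k] <- col
  }
  cl <- vector("list", N)
  for (k in seq_len(N)) {
    tk <- alphabet[k]
    ck <- as.integer(rd(tk - 1L))
    last <- M - sum(ck)
    if (last < 0L)
      stop(sprintf("corrupt container: allele counts at site %d exceed M", k - 1L),
           call. = FALSE)
    cl[[k]] <- c(ck, last)
  }
  cp_pos <- seq.int(0L, M, by = occ_stride)
  occ <- vector("list", N)
  for (k in seq_len(N)) {
    occ[[k]] <- matrix(as.integer(rd(alphabet[k] * length(cp_pos))),
                       nrow = alphabet[k])
  }
  cp_sites <- integer(n_cp)
  cp_a <- vector("list", n_cp)
  for (j in seq_len(n_cp)) {
    cp_sites[j] <- as.integer(rd(1L))
    cp_a[[j]] <- as.integer(rd(M))
  }
  structure(list(y = y, c = cl, occ = occ, occ_stride = occ_stride,
                 occ_positions = cp_pos, cp_sites = cp_sites, cp_a = cp_a,
                 checkpoint_stride = cp_stride, M = M, N = N,
                 alphabet = alphabet),
            class = "mpbwt_transformed")
}

#' Reconstruct the original panel from its transform
#'
#' Starting from the identity prefix array at site 0, scatters each `y_k`
#' through `a_k` into panel column `k` and advances the prefix array with the
#' extension function (`a_{k+1}[w_k(i, y_k[i])] = a_k[i]`). The result equals
#' the panel passed to [pbwt_transform()] element for element.
#'
#' @param tp An `mpbwt_transformed` object.
#' @return A [haplotype_panel].
#' @export
pbwt_reconstruct <- function(tp) {
  stopifnot(inherits(tp, "mpbwt_transformed"))
  M <- tp$M; N <- tp$N
  X <- matrix(0L, nrow = M, ncol = N)
  a <- seq_len(M) - 1L
  for (k in seq_len(N)) {
    yk <- tp$y[, k]
    ck <- tp$c[[k]]
    if (sum(ck) != M || any(ck < 0L))
      stop(sprintf("corrupt transform: allele counts at site %d do not sum to M",
                   k - 1L), call. = FALSE)
    X[a + 1L, k] <- yk
    # vectorized extension: within-allele occurrence number + cumulative counts
    occ_before <- stats::ave(seq_len(M), yk, FUN = seq_along) - 1L
    cc_prev <- c(0L, cumsum(ck))[yk + 1L]
    w <- occ_before + cc_prev
    if (anyDuplicated(w))
      stop(sprintf("corrupt transform: extension at site %d is not a permutation",
                   k - 1L), call. = FALSE)
    anew <- integer(M)
    anew[w + 1L] <- a
    a <- anew
  }
  haplotype_panel(X, alphabet = tp$alphabet)
}

#' Compress a panel to a .mpbwt file / decompress it back
#'
#' `compress_panel()` is `pbwt_transform()` + `pbwt_encode()` + a file write;
#' `decompress_panel()` reads, decodes and reconstructs.
#'
#' @param panel A [haplotype_panel].
#' @param path File path (conventionally `.mpbwt`).
#' @param ... Passed to [pbwt_transform()].
#' @return `compress_panel()`: `path` invisibly; `decompress_panel()`: a
#'   [haplotype_panel].
#' @export
compress_panel <- function(panel, path, ...) {
  bytes <- pbwt_encode(pbwt_transform(panel, ...))
  writeBin(bytes, path)
  invisible(path)
}

#' @rdname compress_panel
#' @export
decompress_panel <- function(path) {
  bytes <- readBin(path, what = "raw", n = file.size(path))
  pbwt_reconstruct(pbwt_decode(bytes))
}
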