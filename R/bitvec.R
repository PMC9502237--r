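#' Bit vector with rank/select support
#'
#' A plain bit sequence augmented with precomputed rank and select
#' directories, the backbone of the per-contig coordinate maps. `rank1()`
#' counts set bits in the half-open prefix `[0, i)`; `select1()` returns the
#' 0-based position of the k-th set bit (k is 1-based). These conventions
#' match the SDSL succinct-data-structure library.
#'
#' The directories are full precomputed tables (a cumulative-sum vector and
#' the positions of all set bits), so both queries are O(1) after an O(n)
#' build. Memory is O(n) words rather than o(n) extra bits; the bit-packed
#' form is used on disk (see [save_index()]).
#'
#' @param bits integer, logical or numeric vector of 0/1 values.
#' @return An object of class `bitvec` with fields `bits` (integer 0/1),
#'   `length`, `rank` (cumulative counts, length `length + 1`) and `sel`
#'   (0-based positions of the set bits).
#' @examples
#' bv <- bitvec(c(1, 0, 1, 1, 0, 1))
#' rank1(bv, 3)   # 2
#' select1(bv, 4) # 5
#' @export
bitvec <- function(bits) {
  bits <- as.integer(bits)
  if (anyNA(bits) || any(bits < 0L | bits > 1L)) {
    stop("bitvec: bits must be 0/1 with no NA")
  }
  structure(
    list(
      bits = bits,
      length = length(bits),
      rank = c(0L, cumsum(bits)),
      sel = which(bits == 1L) - 1L
    ),
    class = "bitvec"
  )
}

#' @export
print.bitvec <- function(x, ...) {
  shown <- if (x$length > 64L) {
    paste0(paste(x$bits[1:64], collapse = ""), "...")
  } else {
    paste(x$bits, collapse = "")
  }
  cat(sprintf("<bitvec> length %d, popcount %d: %s\n",
              x$length, x$rank[x$length + 1L], shown))
  invisible(x)
}

#' Count set bits in a prefix
#'
#' @param bv a [bitvec()].
#' @param i prefix bound(s), `0 <= i <= length(bv)`; the count covers
#'   positions `[0, i)`. Vectorized over `i`.
#' @return integer count(s) of 1-bits in the prefix.
#' @export
rank1 <- function(bv, i) {
  stopifnot(inherits(bv, "bitvec"))
  i <- as.integer(i)
  if (anyNA(i) || any(i < 0L | i > bv$length)) {
    stop(sprintf("rank1: index out of bounds [0, %d]", bv$length))
  }
  bv$rank[i + 1L]
}

#' Position of the k-th set bit
#'
#' @param bv a [bitvec()].
#' @param k 1-based ordinal(s), `1 <= k <= rank1(bv, length(bv))`.
#'   Vectorized over `k`.
#' @return 0-based position(s) of the k-th 1-bit.
#' @export
select1 <- function(bv, k) {
  stopifnot(inherits(bv, "bitvec"))
  k <- as.integer(k)
  n1 <- length(bv$sel)
  if (length(k) == 0L || anyNA(k) || any(k < 1L | k > n1)) {
    stop(sprintf("select1: ordinal out of range [1, %d]", n1))
  }
  bv$sel[k]
}
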