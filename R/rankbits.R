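#' Plain bit vector with constant-time rank
#'
#' Uncompressed rank support: the bits are kept verbatim together with a
#' cumulative count vector, so `rank1(b, i)` is a single lookup. This is the
#' "plain blocks" flavour of rank support; compressed bit vectors are out of
#' scope here.
#'
#' @param bits integer (or logical) vector of 0/1 values.
#' @return object of class `rank_bits`.
#' @export
rank_bits <- function(bits) {
  bits <- as.integer(bits)
  stopifnot(all(bits %in% c(0L, 1L)))
  structure(
    list(bits = bits, rk = c(0L, cumsum(bits)), n = length(bits)),
    class = "rank_bits"
  )
}

#' Number of ones in `b$bits[1..i]`
#'
#' `rank1(b, 0)` is 0; `i` may be a vector.
#' @param b a [rank_bits] object.
#' @param i position(s), 0 <= i <= length of the vector.
#' @export
rank1 <- function(b, i) {
  stopifnot(all(i >= 0L), all(i <= b$n))
  b$rk[i + 1L]
}

#' @export
print.rank_bits <- function(x, ...) {
  cat(sprintf("rank_bits: length %d, %d one(s)\n", x$n, x$rk[x$n + 1L]))
  invisible(x)
}
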