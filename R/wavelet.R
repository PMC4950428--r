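#' Balanced wavelet tree with rank support
#'
#' A balanced binary tree over an integer code range `[lo..hi]`. Each inner
#' node splits the range at its midpoint and stores, for the subsequence of
#' values routed through it, a plain cumulative rank vector of the
#' "go right" bits. Rank of any symbol up to any position therefore costs
#' one lookup per level (about `log2(sigma)` lookups). The same tree is used
#' for the BWT (backward search, `getIntervals`) and for the document array
#' (range-distinct with counts).
#'
#' @param values integer vector of codes.
#' @param lo,hi code range covered by the tree (defaults to the range of
#'   `values`).
#' @return object of class `wavelet_tree`.
#' @export
wavelet_tree <- function(values, lo = min(values), hi = max(values)) {
  values <- as.integer(values)
  lo <- as.integer(lo)
  hi <- as.integer(hi)
  stopifnot(length(values) > 0L, lo <= hi, all(values >= lo), all(values <= hi))
  build <- function(v, lo, hi) {
    if (lo == hi) {
      return(list(lo = lo, hi = hi, leaf = TRUE, size = length(v)))
    }
    mid <- (lo + hi) %/% 2L
    right <- v > mid
    list(
      lo = lo, hi = hi, mid = mid, leaf = FALSE, size = length(v),
      rk = c(0L, cumsum(as.integer(right))),
      left = build(v[!right], lo, mid),
      right = build(v[right], mid + 1L, hi)
    )
  }
  structure(build(values, lo, hi), class = "wavelet_tree")
}

#' Rank of a symbol in a wavelet tree
#'
#' Counts occurrences of code `sym` among the first `i` values of the
#' sequence the tree was built from (`i = 0` gives 0).
#'
#' @param wt a `wavelet_tree`.
#' @param sym integer code.
#' @param i prefix length, `0 <= i <= n`.
#' @export
wt_rank <- function(wt, sym, i) {
  sym <- as.integer(sym)
  i <- as.integer(i)
  stopifnot(i >= 0L, i <= wt$size)
  if (sym < wt$lo || sym > wt$hi) {
    return(0L)
  }
  node <- wt
  while (!node$leaf) {
    r <- node$rk[i + 1L]
    if (sym <= node$mid) {
      i <- i - r
      node <- node$left
    } else {
      i <- r
      node <- node$right
    }
  }
  i
}

# internal: range-distinct with counts. For the value range positions
# (i1..i2] (i.e. prefix counts i1 < i2) returns a matrix with one row per
# distinct code present: cbind(code, r1, r2) where r1/r2 are the
# prefix-counts of that code up to i1 and i2. Rows are in ascending code
# order (left-to-right leaf order).
.wt_intervals <- function(wt, i1, i2) {
  acc <- vector("list", 16L)
  cnt <- 0L
  rec <- function(node, i1, i2) {
    if (node$leaf) {
      cnt <<- cnt + 1L
      acc[[cnt]] <<- c(node$lo, i1, i2)
      return(invisible(NULL))
    }
    r1 <- node$rk[i1 + 1L]
    r2 <- node$rk[i2 + 1L]
    z1 <- i1 - r1
    z2 <- i2 - r2
    if (z2 > z1) rec(node$left, z1, z2)
    if (r2 > r1) rec(node$right, r1, r2)
    invisible(NULL)
  }
  rec(wt, as.integer(i1), as.integer(i2))
  matrix(unlist(acc[seq_len(cnt)], use.names = FALSE), ncol = 3L, byrow = TRUE)
}

#' @export
print.wavelet_tree <- function(x, ...) {
  cat(sprintf(
    "wavelet_tree over codes [%d..%d], sequence length %d\n",
    x$lo, x$hi, x$size
  ))
  invisible(x)
}
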