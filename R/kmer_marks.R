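# Marking of k-mer intervals over the suffix array:
#  B_r marks the left and right boundary of the interval of every
#      right-maximal k-mer (an lcp-interval of lcp-value k);
#  B_l marks positions i such that the k-mer at SA[i] is not right-maximal,
#      i is the right boundary of its interval, and the k-mer one position
#      to the right in the text is a left-maximal repeat.
# Both are derived from the 2-bit LCP level array in one scan.

# internal: maximal runs of LCP codes >= 1, i.e. intervals of repeats of
# length >= k. Returns cbind(lb, rb).
.level_runs <- function(L) {
  z <- which(L == 0L)
  a <- z[-length(z)]
  b <- z[-1L]
  keep <- b > a + 1L
  cbind(lb = a[keep], rb = b[keep] - 1L)
}

#' Mark right-maximal k-mer intervals and seed graph nodes
#'
#' Finds every lcp-interval of lcp-value `k` (boundary LCP entries `< k`,
#' interior entries `>= k`, at least one `= k`): these are exactly the
#' suffix array intervals of right-maximal k-mers. Both boundaries are
#' marked in `B_r`, and for each interval a graph node
#' `(len = k, lb, size, suffix_lb = lb)` is seeded. Intervals are
#' discovered in ascending `lb` order, so seed identifiers
#' `1..rightMax` are lexicographic in the k-mer.
#'
#' @param fm an `fm_index`.
#' @param L an `lcp_levels` object from [compute_lcp_levels()].
#' @param k k-mer length (must match `L$k`).
#' @return list with `B_r` (`rank_bits`), `seeds` (matrix with columns
#'   `len, lb, size, suffix_lb`, one row per node in identifier order),
#'   `rightMax`, and `queue` (the seeded identifiers).
#' @export
mark_right_maximal <- function(fm, L, k = L$k) {
  stopifnot(inherits(L, "lcp_levels"), k == L$k)
  Lv <- L$L
  runs <- .level_runs(Lv)
  c1 <- c(0L, cumsum(Lv == 1L))
  # at least one interior code "= k" (positions lb+1 .. rb)
  has1 <- c1[runs[, 2L] + 1L] - c1[runs[, 1L] + 1L] > 0L
  runs <- runs[has1, , drop = FALSE]
  bits <- integer(fm$n)
  bits[runs[, 1L]] <- 1L
  bits[runs[, 2L]] <- 1L
  rlb <- unname(runs[, 1L])
  rrb <- unname(runs[, 2L])
  seeds <- cbind(
    len = rep.int(as.integer(k), nrow(runs)),
    lb = rlb,
    size = rrb - rlb + 1L,
    suffix_lb = rlb
  )
  list(
    B_r = rank_bits(bits), seeds = seeds,
    rightMax = nrow(runs), queue = seq_len(nrow(runs))
  )
}

#' Mark non-right-maximal k-mers preceding left-maximal k-mers
#'
#' For every interval `[lb..rb]` of a repeat of length `>= k` that is
#' left-maximal (its BWT range contains at least two distinct symbols,
#' detected via the last index at which consecutive BWT symbols differ),
#' the position `LF(q)` is set in `B_l` for each distinct non-separator
#' symbol `c` in `BWT[lb..rb]`, `q` being the last occurrence of `c` in
#' that range. One-bits that fall inside a right-maximal k-mer interval are
#' then cleared (those k-mers are already covered by `B_r`).
#'
#' @param fm an `fm_index`.
#' @param L an `lcp_levels` object.
#' @param B_r the `rank_bits` from [mark_right_maximal()].
#' @param k k-mer length (must match `L$k`).
#' @return list with `B_l` (`rank_bits`) and `leftMax`.
#' @export
mark_bl <- function(fm, L, B_r, k = L$k) {
  stopifnot(inherits(L, "lcp_levels"), k == L$k)
  runs <- .level_runs(L$L)
  bits <- integer(fm$n)
  bwt <- fm$bwt_codes
  lf <- fm$lf
  for (r in seq_len(nrow(runs))) {
    lb <- runs[r, 1L]
    rb <- runs[r, 2L]
    sub <- bwt[lb:rb]
    if (all(sub == sub[1L])) {
      next # not left-maximal: lastdiff <= lb
    }
    for (cc in unique(sub)) {
      if (cc <= 1L) {
        next # separator symbols never start a graph node
      }
      q <- lb - 1L + max(which(sub == cc))
      bits[lf[q]] <- 1L
    }
  }
  # clear marks of right-maximal k-mers (already covered by B_r)
  ones <- which(bits == 1L)
  if (length(ones)) {
    rk <- rank1(B_r, ones)
    inside <- (rk %% 2L == 1L) | (B_r$bits[ones] == 1L)
    bits[ones[inside]] <- 0L
  }
  list(B_l = rank_bits(bits), leftMax = sum(bits))
}

#' k-mer interval marks for graph construction
#'
#' Convenience wrapper running [compute_lcp_levels()],
#' [mark_right_maximal()] and [mark_bl()] for one `k`.
#'
#' @param fm an `fm_index`.
#' @param k k-mer length, `2 <= k < min(sequence lengths)`.
#' @return object of class `kmer_marks`: list with `B_r`, `B_l`,
#'   `rightMax`, `leftMax`, `k`, `seeds`, and the level array `L`.
#' @examples
#' fm <- build_fm_index(encode_and_concatenate(c(x = "ACTACGTACGTACG")))
#' mk <- kmer_marks(fm, 3)
#' which(mk$B_r$bits == 1L) # 2 4
#' which(mk$B_l$bits == 1L) # 9 12
#' @export
kmer_marks <- function(fm, k) {
  L <- compute_lcp_levels(fm, k)
  mr <- mark_right_maximal(fm, L, k)
  ml <- mark_bl(fm, L, mr$B_r, k)
  structure(
    list(
      B_r = mr$B_r, B_l = ml$B_l,
      rightMax = mr$rightMax, leftMax = ml$leftMax,
      k = as.integer(k), seeds = mr$seeds, L = L
    ),
    class = "kmer_marks"
  )
}

#' @export
print.kmer_marks <- function(x, ...) {
  cat(sprintf(
    "kmer_marks: k = %d, rightMax = %d, leftMax = %d\n",
    x$k, x$rightMax, x$leftMax
  ))
  invisible(x)
}
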