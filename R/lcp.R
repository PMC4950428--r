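# LCP computation directly from the BWT via breadth-first interval
# extension: the omega-interval of every string of length l yields, through
# getIntervals, the c*omega-intervals; the entry LCP[j+1] at the right
# boundary j of a newly seen interval equals l. Entries are therefore
# produced in ascending order of their value, which lets us stop at level k
# and keep only a 2-bit classification per entry.
#
# Separator semantics: the d-1 occurrences of '#' are treated as pairwise
# distinct characters. This is achieved purely through seeding: instead of
# the single '#'-interval [2..d], the breadth-first search starts from the
# d-1 singleton intervals [s..s], 2 <= s <= d, so no comparison ever
# extends across a separator.

# internal engine: returns the LCP values (length n+1, -1 at both ends)
# materializing only entries <= maxval; others stay NA.
.lcp_entries <- function(fm, maxval = Inf) {
  n <- fm$n
  d <- fm$text$d
  vals <- rep(NA_integer_, n + 1L)
  vals[1L] <- -1L
  vals[n + 1L] <- -1L
  filled <- logical(n + 1L)
  filled[1L] <- TRUE
  filled[n + 1L] <- TRUE
  m <- .gi(fm, 1L, n)
  cur <- m[, c(2L, 3L), drop = FALSE]
  if (d > 1L) {
    cur <- cur[m[, 1L] != 1L, , drop = FALSE]
    cur <- rbind(cur, cbind(2:d, 2:d))
  }
  g <- 1L # current generation: intervals of strings of length g
  while (nrow(cur) > 0L && g - 1L <= maxval) {
    p <- cur[, 2L] + 1L
    new <- !filled[p]
    filled[p[new]] <- TRUE
    vals[p[new]] <- g - 1L
    cur <- cur[new, , drop = FALSE]
    if (g - 1L == maxval || nrow(cur) == 0L) {
      break
    }
    kids <- vector("list", nrow(cur))
    for (r in seq_len(nrow(cur))) {
      gm <- .gi(fm, cur[r, 1L], cur[r, 2L])
      kids[[r]] <- gm[, c(2L, 3L), drop = FALSE]
    }
    cur <- do.call(rbind, kids)
    g <- g + 1L
  }
  vals
}

#' Full LCP array from the BWT
#'
#' Computes the complete LCP array (positions `1..n+1`, with `-1` at both
#' ends) of the pan-genome text under the modified comparison order in
#' which distinct occurrences of the separator `#` are mutually
#' incomparable. Provided mainly for validation and small-scale inspection;
#' the construction itself only ever needs the 2-bit level array of
#' [compute_lcp_levels()].
#'
#' @param fm an `fm_index`.
#' @return integer vector of length `n + 1`.
#' @export
lcp_from_bwt <- function(fm) {
  v <- .lcp_entries(fm, Inf)
  if (anyNA(v)) {
    stop("pancdbg_internal: LCP breadth-first search left entries unset")
  }
  v
}

#' Two-bit LCP level array for a given k
#'
#' Classifies every LCP entry against `k`: code 0 for `LCP < k`, code 1 for
#' `LCP = k`, code 2 for `LCP > k`. Only levels `0..k` of the breadth-first
#' LCP computation are run, so entries with larger values are never
#' materialized.
#'
#' @param fm an `fm_index`.
#' @param k k-mer length, `2 <= k < min(sequence lengths)`.
#' @param d number of sequences (defaults to the indexed text's `d`).
#' @return object of class `lcp_levels`: list with `L` (integer codes,
#'   length `n + 1`), `k`, `n`.
#' @export
compute_lcp_levels <- function(fm, k, d = fm$text$d) {
  k <- as.integer(k)
  if (k < 2L || k >= min(fm$text$seq_lengths)) {
    stop("pancdbg_bad_k: need 2 <= k < min(sequence lengths)")
  }
  stopifnot(d == fm$text$d)
  v <- .lcp_entries(fm, maxval = k)
  L <- rep(2L, fm$n + 1L)
  L[!is.na(v) & v < k] <- 0L
  L[!is.na(v) & v == k] <- 1L
  structure(list(L = L, k = k, n = fm$n), class = "lcp_levels")
}

#' @export
print.lcp_levels <- function(x, ...) {
  cat(sprintf(
    "lcp_levels: k = %d, codes <k/=k/>k: %d/%d/%d\n",
    x$k, sum(x$L == 0L), sum(x$L == 1L), sum(x$L == 2L)
  ))
  invisible(x)
}
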