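# FM-index of the concatenated pan-genome: suffix array, BWT, C-array,
# wavelet tree with rank, LF / Psi, backward search and the generalized
# one-symbol left extension getIntervals.

# internal: suffix array by prefix doubling on integer codes. The sentinel
# (code 0, unique, at the end) guarantees all suffixes are distinct.
# Vectorized O(n log^2 n); ample at the problem sizes this package targets.
.sa_prefix_doubling <- function(codes) {
  n <- length(codes)
  if (n == 1L) {
    return(1L)
  }
  rk <- codes
  h <- 1L
  repeat {
    key2 <- if (h < n) c(rk[(1L + h):n], rep.int(-1L, h)) else rep.int(-1L, n)
    o <- order(rk, key2, method = "radix")
    r1 <- rk[o]
    r2 <- key2[o]
    new_rk <- cumsum(c(1L, (r1[-1L] != r1[-n]) | (r2[-1L] != r2[-n])))
    rk[o] <- new_rk
    if (new_rk[n] == n) {
      return(o)
    }
    h <- h * 2L
  }
}

#' Build the FM-index of a pan-genome text
#'
#' Computes the suffix array `SA`, the Burrows-Wheeler transform
#' `BWT[i] = S[SA[i]-1]` (with `BWT[i] = '$'` where `SA[i] = 1`), the
#' C-array (for each symbol, the number of strictly smaller symbols in `S`),
#' a wavelet tree over the BWT, per-symbol cumulative occurrence counts
#' (plain rank blocks), and the full `LF` / `Psi` permutations.
#'
#' @param text a `pan_text` from [encode_and_concatenate()].
#' @return object of class `fm_index`. Components of note: `sa`, `bwt`
#'   (character string), `bwt_codes`, `C` (indexed by code + 1), `wt`,
#'   `lf`, `psi_v`, plus the originating `text`.
#' @examples
#' fm <- build_fm_index(encode_and_concatenate(c(x = "ACTACGTACGTACG")))
#' fm$sa[1:5] # 15 12 8 4 1
#' @export
build_fm_index <- function(text) {
  stopifnot(inherits(text, "pan_text"))
  n <- text$n
  sigma <- text$sigma
  sa <- .sa_prefix_doubling(text$codes)
  prev <- ifelse(sa == 1L, n, sa - 1L)
  bwt_codes <- text$codes[prev]
  tab <- tabulate(bwt_codes + 1L, nbins = sigma)
  C <- c(0L, cumsum(tab))[seq_len(sigma)] # C[code + 1]
  # plain cumulative occurrence counts, one vector per symbol: occ[[c+1]][i+1]
  # is the number of occurrences of code c in BWT[1..i]
  occ <- lapply(seq_len(sigma) - 1L, function(cc) {
    c(0L, cumsum(bwt_codes == cc))
  })
  # per-position rank of BWT[i] among its equals in BWT[1..i]
  rnk <- integer(n)
  for (cc in seq_len(sigma) - 1L) {
    idx <- which(bwt_codes == cc)
    rnk[idx] <- seq_along(idx)
  }
  lf <- C[bwt_codes + 1L] + rnk
  psi_v <- integer(n)
  psi_v[lf] <- seq_len(n)
  structure(
    list(
      text = text, n = n, sigma = sigma, sa = sa,
      bwt_codes = bwt_codes,
      bwt = paste(text$alphabet[bwt_codes + 1L], collapse = ""),
      C = C, occ = occ,
      wt = wavelet_tree(bwt_codes, 0L, sigma - 1L),
      lf = lf, psi_v = psi_v
    ),
    class = "fm_index"
  )
}

#' @export
print.fm_index <- function(x, ...) {
  cat(sprintf(
    "fm_index: n = %d, sigma = %d, %d sequence(s)\n",
    x$n, x$sigma, x$text$d
  ))
  invisible(x)
}

#' Suffix array intervals
#'
#' Closed, 1-based interval `[lb..rb]` into the suffix array; `lb > rb`
#' encodes the empty interval.
#' @param lb,rb boundaries.
#' @export
interval <- function(lb, rb) {
  c(lb = as.integer(lb), rb = as.integer(rb))
}

#' @rdname interval
#' @param iv an interval.
#' @export
is_empty_interval <- function(iv) {
  iv[[1L]] > iv[[2L]]
}

.check_index <- function(fm, i) {
  if (length(i) != 1L || is.na(i) || i < 1L || i > fm$n) {
    stop("pancdbg_index_out_of_range: need 1 <= i <= n")
  }
}

#' Last-to-first mapping
#'
#' `lf_map(fm, i)` is the suffix array index `j` with `SA[j] = SA[i] - 1`
#' (and 1 when `SA[i] = 1`), computed as `C[BWT[i]] + rank_BWT[i](i)` on the
#' wavelet tree.
#'
#' @param fm an `fm_index`.
#' @param i suffix array index, 1-based.
#' @export
lf_map <- function(fm, i) {
  .check_index(fm, i)
  cc <- fm$bwt_codes[i]
  fm$C[cc + 1L] + wt_rank(fm$wt, cc, i)
}

#' Inverse of the last-to-first mapping
#'
#' `psi(fm, lf_map(fm, i)) == i` for every `i`; served from the precomputed
#' inverse permutation.
#'
#' @inheritParams lf_map
#' @export
psi <- function(fm, i) {
  .check_index(fm, i)
  fm$psi_v[i]
}

#' One backward search step
#'
#' Given the `w`-interval of some (possibly empty) string `w` and a symbol
#' `c`, returns the `cw`-interval; the empty interval when `cw` does not
#' occur in `S` (or `c` is not in the alphabet).
#'
#' @param fm an `fm_index`.
#' @param c single character.
#' @param iv interval, e.g. `interval(1, fm$n)` for the empty string.
#' @examples
#' fm <- build_fm_index(encode_and_concatenate(c(x = "ACTACGTACGTACG")))
#' backward_search(fm, "T", interval(2, 4)) # the TACG-interval [13..15]
#' @export
backward_search <- function(fm, c, iv) {
  code <- match(c, fm$text$alphabet) - 1L
  if (is.na(code)) {
    return(interval(1L, 0L))
  }
  ov <- fm$occ[[code + 1L]]
  lb <- fm$C[code + 1L] + ov[iv[[1L]]] + 1L
  rb <- fm$C[code + 1L] + ov[iv[[2L]] + 1L]
  interval(lb, rb)
}

# internal backward step on codes; returns c(lb, rb)
.bs_code <- function(fm, code, lb, rb) {
  ov <- fm$occ[[code + 1L]]
  base <- fm$C[code + 1L]
  c(base + ov[lb] + 1L, base + ov[rb + 1L])
}

# internal getIntervals: matrix with rows (code, i, j), ascending code order
.gi <- function(fm, lb, rb) {
  m <- .wt_intervals(fm$wt, lb - 1L, rb)
  cbind(
    code = m[, 1L],
    i = fm$C[m[, 1L] + 1L] + m[, 2L] + 1L,
    j = fm$C[m[, 1L] + 1L] + m[, 3L]
  )
}

#' Generalized backward extension (getIntervals)
#'
#' For a non-empty `w`-interval, returns every pair `(c, cw-interval)` such
#' that `cw` is a substring of `S`, including the separator symbols `#` and
#' `$` when they precede `w`. Pairs are returned in ascending alphabet
#' order; the returned intervals are disjoint and their sizes sum to the
#' size of the input interval.
#'
#' @param fm an `fm_index`.
#' @param iv non-empty interval.
#' @return list of `list(symbol =, lb =, rb =)`.
#' @examples
#' fm <- build_fm_index(encode_and_concatenate(c(x = "ACTACGTACGTACG")))
#' get_intervals(fm, interval(13, 15)) # [(C,[9..9]), (G,[11..12])]
#' @export
get_intervals <- function(fm, iv) {
  if (is_empty_interval(iv)) {
    stop("pancdbg_empty_interval: getIntervals needs a non-empty interval")
  }
  m <- .gi(fm, iv[[1L]], iv[[2L]])
  lapply(seq_len(nrow(m)), function(r) {
    list(
      symbol = fm$text$alphabet[m[r, 1L] + 1L],
      lb = unname(m[r, 2L]), rb = unname(m[r, 3L])
    )
  })
}
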