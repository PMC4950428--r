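# Pattern search on the implicit graph and per-sequence membership queries
# through a document array.

#' Build the document array
#'
#' `D[i]` is the number of the sequence owning suffix array position `i`
#' (a terminator belongs to the sequence it ends; `'$'` belongs to the last
#' sequence). `D` is stored in a wavelet tree so that range-distinct with
#' counts over any suffix array interval is a single tree descent.
#'
#' @param fm an `fm_index`.
#' @param text the indexed `pan_text` (defaults to `fm$text`).
#' @return object of class `doc_array` with components `D`, `wt`, `d`, `n`.
#' @export
build_document_array <- function(fm, text = fm$text) {
  D <- .seq_of_position(text, fm$sa)
  structure(
    list(D = D, wt = wavelet_tree(D, 1L, text$d), d = text$d, n = fm$n),
    class = "doc_array"
  )
}

#' @export
print.doc_array <- function(x, ...) {
  cat(sprintf("doc_array: n = %d, %d sequence(s)\n", x$n, x$d))
  invisible(x)
}

#' Sequences covered by a suffix array interval
#'
#' Range-distinct with counts over `D[lb..rb]`: one row per sequence in
#' which the interval's string occurs, in ascending sequence number, with
#' the occurrence count.
#'
#' @param doc a `doc_array`.
#' @param iv suffix array interval; an empty interval yields zero rows.
#' @return `data.frame` with columns `seq` and `count`.
#' @export
interval_sequences <- function(doc, iv) {
  if (is_empty_interval(iv)) {
    return(data.frame(seq = integer(0L), count = integer(0L)))
  }
  m <- .wt_intervals(doc$wt, iv[[1L]] - 1L, iv[[2L]])
  data.frame(seq = m[, 1L], count = m[, 3L] - m[, 2L])
}

#' Sequences containing a node
#'
#' [interval_sequences()] applied to the node's suffix array interval.
#'
#' @param doc a `doc_array`.
#' @param G an `implicit_cdbg`.
#' @param id node identifier.
#' @export
node_sequences <- function(doc, G, id) {
  .check_id(G, id)
  interval_sequences(doc, interval(G$lb[id], G$lb[id] + G$size[id] - 1L))
}

#' Find the node owning a suffix array interval
#'
#' Given the non-empty interval of a string `u` of length `>= k` that is a
#' suffix of some node string (in particular any full k-mer interval),
#' iterates: a left boundary `<= d` identifies a stop node; an interval
#' inside a right-maximal k-mer interval identifies the node via `B_r`; a
#' one-bit of `B_l` at the right boundary identifies a split node;
#' otherwise `Psi` is applied to both boundaries (dropping the first
#' character of `u`) and the iteration continues.
#'
#' @param fm an `fm_index`.
#' @param marks a `kmer_marks` object.
#' @param G an `implicit_cdbg`.
#' @param iv non-empty suffix array interval.
#' @param d number of sequences (defaults to the indexed text's).
#' @return list with `id` (owning node) and `ell`, the normalized number of
#'   Psi applications: the node string has `G$len[id] - ell - k` characters
#'   in front of the queried k-mer's occurrence (for stop nodes `ell`
#'   already includes the `+1-k` adjustment for the terminator).
#' @export
locate_node_of_interval <- function(fm, marks, G, iv, d = fm$text$d) {
  if (is_empty_interval(iv)) {
    stop("pancdbg_empty_interval")
  }
  i <- iv[[1L]]
  j <- iv[[2L]]
  k <- G$k
  rightMax <- G$rightMax
  leftMax <- G$leftMax
  Brbits <- marks$B_r$bits
  Brrk <- marks$B_r$rk
  Blbits <- marks$B_l$bits
  Blrk <- marks$B_l$rk
  psiv <- fm$psi_v
  steps <- 0L
  repeat {
    if (i <= d) {
      return(list(id = rightMax + leftMax + i, ell = steps + 1L - k))
    }
    rk <- Brrk[i + 1L]
    if (rk %% 2L == 1L || Brbits[i] == 1L) {
      return(list(id = (rk + 1L) %/% 2L, ell = steps))
    }
    if (Blbits[j] == 1L) {
      return(list(id = rightMax + Blrk[i] + 1L, ell = steps))
    }
    if (steps > fm$n) {
      stop("pancdbg_inconsistent_graph: interval reached no node marker")
    }
    i <- psiv[i]
    j <- psiv[j]
    steps <- steps + 1L
  }
}

.empty_search <- function(P, k) {
  structure(
    list(
      pattern = P, k = k, found = FALSE,
      res_list = integer(0L), interval = interval(1L, 0L),
      offset = NA_integer_
    ),
    class = "cdbg_search"
  )
}

#' Search a pattern in the compressed de Bruijn graph
#'
#' Locates the ordered list of nodes whose strings spell the pattern `P`
#' (`|P| >= k`, no separator symbols): the suffix array interval of the
#' k-mer suffix of `P` is found by backward search and mapped to its
#' owning node with [locate_node_of_interval()]; the remaining characters
#' are then consumed right to left, one backward search step each, and a
#' predecessor node is resolved through `B_r`/`B_l` whenever a node
#' boundary is crossed.
#'
#' @param fm an `fm_index`.
#' @param marks a `kmer_marks` object.
#' @param G an `implicit_cdbg`.
#' @param P pattern string (symbols absent from the alphabet give an empty
#'   result; separator symbols or `nchar(P) < k` are an error).
#' @param k k-mer length (defaults to the graph's).
#' @return object of class `cdbg_search`: `found`, `res_list` (node path,
#'   first to last), `interval` (suffix array interval of the whole
#'   pattern), and `offset` (number of characters of the first node's
#'   string that precede the pattern's first k-mer).
#' @examples
#' fm <- build_fm_index(encode_and_concatenate(c(x = "ACTACGTACGTACG")))
#' mk <- kmer_marks(fm, 3)
#' g <- build_implicit(fm, mk)
#' search_pattern(fm, mk, g, "ACGTACG")$res_list # 1 3 1
#' @export
search_pattern <- function(fm, marks, G, P, k = G$k) {
  m <- nchar(P)
  if (m < k) {
    stop("pancdbg_pattern_too_short: need nchar(P) >= k")
  }
  chars <- strsplit(toupper(P), "", fixed = TRUE)[[1L]]
  if (any(chars == "$" | chars == "#")) {
    stop("pancdbg_reserved_symbol: patterns must not contain '$' or '#'")
  }
  codes <- match(chars, fm$text$alphabet) - 1L
  if (anyNA(codes)) {
    return(.empty_search(P, k))
  }
  occ <- fm$occ
  Cv <- fm$C
  lb <- 1L
  rb <- fm$n
  for (t in m:(m - k + 1L)) {
    cc <- codes[t] + 1L
    ov <- occ[[cc]]
    lb <- Cv[cc] + ov[lb] + 1L
    rb <- Cv[cc] + ov[rb + 1L]
    if (lb > rb) {
      return(.empty_search(P, k))
    }
  }
  loc <- locate_node_of_interval(fm, marks, G, interval(lb, rb))
  id <- loc$id
  Glen <- G$len
  ell <- Glen[id] - loc$ell - k
  resr <- id # reversed path; predecessors are appended
  rightMax <- G$rightMax
  Brbits <- marks$B_r$bits
  Brrk <- marks$B_r$rk
  Blrk <- marks$B_l$rk
  pos <- m - k
  while (pos >= 1L) {
    cc <- codes[pos] + 1L
    ov <- occ[[cc]]
    lb <- Cv[cc] + ov[lb] + 1L
    rb <- Cv[cc] + ov[rb + 1L]
    if (lb > rb) {
      return(.empty_search(P, k))
    }
    pos <- pos - 1L
    if (ell > 0L) {
      ell <- ell - 1L
    } else {
      rk <- Brrk[lb + 1L]
      if (rk %% 2L == 1L || Brbits[lb] == 1L) {
        id <- (rk + 1L) %/% 2L
      } else {
        id <- rightMax + Blrk[lb] + 1L
      }
      resr[length(resr) + 1L] <- id
      ell <- Glen[id] - k
    }
  }
  structure(
    list(
      pattern = P, k = k, found = TRUE,
      res_list = rev(resr), interval = interval(lb, rb),
      offset = ell
    ),
    class = "cdbg_search"
  )
}

#' @export
print.cdbg_search <- function(x, ...) {
  if (!x$found) {
    cat(sprintf("pattern %s: not found\n", x$pattern))
  } else {
    cat(sprintf(
      "pattern %s: node path [%s], %d occurrence(s)\n",
      x$pattern, paste(x$res_list, collapse = " -> "),
      x$interval[[2L]] - x$interval[[1L]] + 1L
    ))
  }
  invisible(x)
}

#' Occurrence positions of a search result
#'
#' Sorted 1-based start positions in `S` of the full pattern, read off the
#' final suffix array interval.
#'
#' @param fm an `fm_index`.
#' @param res a `cdbg_search` result.
#' @export
search_occurrences <- function(fm, res) {
  if (!res$found) {
    return(integer(0L))
  }
  sort(fm$sa[res$interval[[1L]]:res$interval[[2L]]])
}
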