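# Deliberately naive reference implementations used as ground truth in the
# test suite: quadratic suffix sort, pairwise LCP with per-occurrence
# separator symbols, and compressed de Bruijn graph construction by
# enumerating k-windows and compacting non-branching chains in a
# dictionary. No code is shared with the production build path.

#' Naive suffix sort
#'
#' Sorts all suffixes of a `pan_text` by materializing them as strings
#' (after an order-preserving remap of the alphabet codes into printable
#' bytes) and radix-sorting. Quadratic in memory and time; reference only.
#'
#' @param text a `pan_text`.
#' @return the suffix array as an integer permutation of `1..n`.
#' @export
oracle_suffix_sort <- function(text) {
  stopifnot(inherits(text, "pan_text"))
  n <- text$n
  stopifnot(text$sigma <= 90L)
  s2 <- intToUtf8(text$codes + 33L)
  order(substring(s2, seq_len(n)), method = "radix")
}

#' Naive LCP array with distinct separators
#'
#' Computes `LCP[i] = |lcp(S_SA[i-1], S_SA[i])|` by direct pairwise
#' comparison, under the modified order in which distinct occurrences of
#' `'#'` are mutually incomparable: a common prefix never extends to or
#' past a separator.
#'
#' @param text a `pan_text`.
#' @param sa suffix array (defaults to [oracle_suffix_sort()]).
#' @return integer vector of length `n + 1` with `-1` at positions 1 and
#'   `n + 1`.
#' @export
oracle_lcp <- function(text, sa = oracle_suffix_sort(text)) {
  n <- text$n
  codes <- text$codes
  out <- integer(n + 1L)
  out[1L] <- -1L
  out[n + 1L] <- -1L
  for (t in 2:n) {
    a <- sa[t - 1L]
    b <- sa[t]
    L <- min(n - a, n - b) + 1L
    x <- codes[a:(a + L - 1L)]
    y <- codes[b:(b + L - 1L)]
    neq <- which(x != y)
    ml <- if (length(neq)) neq[1L] - 1L else L
    if (ml > 0L) {
      sep <- which(x[seq_len(ml)] <= 1L)
      if (length(sep)) ml <- sep[1L] - 1L
    }
    out[t] <- ml
  }
  out
}

# internal: render a window token as the plain characters it stands for
# (terminator tokens "#<j>" collapse back to "#")
.tok_plain <- function(tok) {
  sub("#[0-9]+$", "#", tok)
}

#' Brute-force compressed de Bruijn graph
#'
#' Builds the uncompressed de Bruijn graph over the k-windows of every
#' sequence followed by its terminator (each separator occurrence treated
#' as a unique symbol, and each sequence start guarded by a virtual unique
#' predecessor so that start nodes are never merged away), puts edges only
#' between consecutive windows of the same sequence, and merges `u, v`
#' whenever `u` is the only distinct predecessor of `v` and `v` the only
#' distinct successor of `u`.
#'
#' @param sequences character vector of sequences (uppercased internally).
#' @param k k-mer length, `<=` every sequence length.
#' @return object of class `oracle_cdbg`: `node_str` (plain node strings),
#'   `node_pos` (list of sorted global start positions in `S`),
#'   `node_len`, `walks` (per-sequence node index visit sequences),
#'   `win_node`/`win_off` (owner node index and offset within the node for
#'   every global window position; `NA` elsewhere), `d`, `k`, `n`.
#' @export
oracle_compressed_dbg <- function(sequences, k) {
  sequences <- toupper(unlist(sequences, use.names = FALSE))
  d <- length(sequences)
  k <- as.integer(k)
  lens <- nchar(sequences)
  stopifnot(d >= 1L, all(lens >= k))
  starts <- cumsum(c(1L, lens[-d] + 1L))
  n <- sum(lens) + d
  term_tok <- c(if (d > 1L) paste0("#", seq_len(d - 1L)), "$")
  win_tok <- vector("list", d)
  win_gpos <- vector("list", d)
  for (j in seq_len(d)) {
    L <- lens[j]
    sj <- sequences[j]
    nw <- L + 2L - k
    toks <- character(nw)
    if (nw >= 2L) {
      toks[seq_len(nw - 1L)] <- substring(sj, seq_len(nw - 1L), seq_len(nw - 1L) + k - 1L)
    }
    toks[nw] <- paste0(substr(sj, nw, L), term_tok[j])
    win_tok[[j]] <- toks
    win_gpos[[j]] <- starts[j] + seq_len(nw) - 1L
  }
  # distinct-successor / distinct-predecessor maps over window tokens,
  # with a virtual unique predecessor "$start<j>" for each sequence start
  from <- character(0L)
  to <- character(0L)
  for (j in seq_len(d)) {
    toks <- win_tok[[j]]
    nw <- length(toks)
    if (nw >= 2L) {
      from <- c(from, toks[-nw])
      to <- c(to, toks[-1L])
    }
    from <- c(from, paste0("$start", j))
    to <- c(to, toks[1L])
  }
  succ <- lapply(split(to, from), unique)
  pred <- lapply(split(from, to), unique)
  all_tok <- unique(unlist(win_tok, use.names = FALSE))
  all_tok <- sort(all_tok, method = "radix") # deterministic head order
  mergeable <- vapply(all_tok, function(v) {
    pv <- pred[[v]]
    if (length(pv) != 1L || pv == v || startsWith(pv, "$start")) {
      return(FALSE)
    }
    length(succ[[pv]]) == 1L
  }, logical(1L))
  names(mergeable) <- all_tok
  heads <- all_tok[!mergeable]
  pos_by_tok <- split(
    unlist(win_gpos, use.names = FALSE),
    unlist(win_tok, use.names = FALSE)
  )
  n_nodes <- length(heads)
  node_str <- character(n_nodes)
  node_pos <- vector("list", n_nodes)
  tok2node <- integer(length(all_tok))
  names(tok2node) <- all_tok
  tok2off <- tok2node
  for (h in seq_len(n_nodes)) {
    cur <- heads[h]
    chain <- cur
    guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > length(all_tok) + 1L) {
        stop("pancdbg_internal: oracle chain did not terminate")
      }
      sc <- succ[[cur]]
      if (is.null(sc) || length(sc) != 1L) break
      if (sc == cur || !mergeable[[sc]]) break
      # sc is mergeable and its unique predecessor is necessarily cur
      chain[length(chain) + 1L] <- sc
      cur <- sc
    }
    plain <- .tok_plain(chain)
    node_str[h] <- paste0(
      plain[1L],
      paste(substring(plain[-1L], k, k), collapse = "")
    )
    node_pos[[h]] <- sort(pos_by_tok[[chain[1L]]])
    tok2node[chain] <- h
    tok2off[chain] <- seq_along(chain) - 1L
  }
  win_node <- rep(NA_integer_, n)
  win_off <- rep(NA_integer_, n)
  for (j in seq_len(d)) {
    win_node[win_gpos[[j]]] <- tok2node[win_tok[[j]]]
    win_off[win_gpos[[j]]] <- tok2off[win_tok[[j]]]
  }
  walks <- lapply(seq_len(d), function(j) {
    nd <- tok2node[win_tok[[j]]]
    of <- tok2off[win_tok[[j]]]
    unname(nd[of == 0L])
  })
  structure(
    list(
      node_str = node_str,
      node_pos = lapply(node_pos, unname),
      node_len = nchar(node_str),
      walks = walks, win_node = win_node, win_off = win_off,
      win_tok = win_tok, win_gpos = win_gpos,
      d = d, k = k, n = n,
      seq_lengths = lens, seq_starts = starts
    ),
    class = "oracle_cdbg"
  )
}

#' @export
print.oracle_cdbg <- function(x, ...) {
  cat(sprintf(
    "oracle_cdbg: k = %d, %d node(s), %d sequence(s)\n",
    x$k, length(x$node_str), x$d
  ))
  invisible(x)
}

#' Owner node of a window
#'
#' The node whose string covers the `t`-th k-window of sequence `j`
#' (windows of `S^j` followed by its terminator).
#'
#' @param g an `oracle_cdbg`.
#' @param j sequence number.
#' @param t window position, `1 <= t <= |S^j| + 2 - k`.
#' @return the owning node's plain string.
#' @export
oracle_window_owner <- function(g, j, t) {
  stopifnot(j >= 1L, j <= g$d)
  nw <- length(g$win_tok[[j]])
  if (t < 1L || t > nw) {
    stop("pancdbg_index_out_of_range: invalid window position")
  }
  g$node_str[g$win_node[g$win_gpos[[j]][t]]]
}

# internal: expected node path for a pattern occurrence starting at global
# position p with m-k+1 windows: collapse window owners at offset-0
# boundaries.
.oracle_pattern_path <- function(g, p, m) {
  idx <- p:(p + m - g$k)
  nd <- g$win_node[idx]
  of <- g$win_off[idx]
  nd[c(TRUE, of[-1L] == 0L)]
}

#' Brute-force edge count of the compressed de Bruijn graph
#'
#' Counts positions `i` in `1..n-k` whose k-mer (with per-occurrence
#' separator symbols) is either a right-maximal k-mer repeat or a
#' non-right-maximal k-mer followed at some occurrence by a left-maximal
#' k-mer repeat. This equals the number of edges.
#'
#' @param text a `pan_text`.
#' @param k k-mer length.
#' @export
oracle_edge_count <- function(text, k) {
  n <- text$n
  k <- as.integer(k)
  toks <- strsplit(text$S, "", fixed = TRUE)[[1L]]
  seps <- which(text$codes == 1L)
  toks[seps] <- paste0("#", seq_along(seps))
  np <- n - k + 1L
  km <- do.call(paste0, lapply(0:(k - 1L), function(o) toks[(1L + o):(np + o)]))
  occ <- split(seq_len(np), km)
  follower <- c(toks[(1L + k):n]) # defined for i in 1..n-k
  preceder <- c("$virtual0", toks[seq_len(n - k)]) # token before position i
  right_max <- vapply(occ, function(ii) {
    ii <- ii[ii <= n - k]
    length(ii) >= 2L && length(unique(follower[ii])) >= 2L
  }, logical(1L))
  left_max <- vapply(occ, function(ii) {
    length(ii) >= 2L && length(unique(preceder[ii])) >= 2L
  }, logical(1L))
  v1 <- km %in% names(occ)[right_max]
  follow_km <- c(km[-1L], NA_character_)
  # separator-spanning k-mers are not k-mers of any sequence and can never
  # end a node; they are excluded from V2 even when the k-mer one position
  # to the right (a sequence-start k-mer) is left-maximal
  in_v2_here <- !v1 & !is.na(follow_km) & !grepl("[#$]", km) &
    follow_km %in% names(occ)[left_max]
  # V2 membership is per k-mer string, through any of its positions
  v2_strings <- unique(km[in_v2_here])
  ii <- seq_len(n - k)
  sum(v1[ii] | km[ii] %in% v2_strings)
}
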