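# Construction of the implicit compressed de Bruijn graph: starting from
# the right-maximal k-mer nodes and one stop node per sequence, every node
# is extended to the left character by character with getIntervals. The
# extension of a node string w stops on a branch whose k-prefix of c*w is a
# right-maximal repeat (a predecessor node ends there, found through B_r);
# if w itself is left-maximal (getIntervals returned more than one pair),
# each surviving branch spawns a split node identified through B_l.

#' Is an interval a subinterval of a right-maximal k-mer interval?
#'
#' Constant-time test on `B_r`: the interval `[i..j]` is *not* such a
#' subinterval if and only if `rank1(B_r, i)` is even and `B_r[i] = 0`
#' (the marked intervals are pairwise disjoint, so the parity of the rank
#' tells whether `i` lies strictly inside one, and the bit itself catches
#' the right boundary).
#'
#' @param marks a `kmer_marks` object (or any list with `B_r`).
#' @param iv non-empty interval.
#' @export
in_right_maximal <- function(marks, iv) {
  if (is_empty_interval(iv)) {
    stop("pancdbg_empty_interval")
  }
  i <- iv[[1L]]
  r <- rank1(marks$B_r, i)
  (r %% 2L == 1L) || (marks$B_r$bits[i] == 1L)
}

#' Identifier of the node ending with a right-maximal k-mer
#'
#' For an index `lb` inside a right-maximal k-mer interval, the node
#' identifier is `floor((rank1(B_r, lb) + 1) / 2)` - valid because the
#' marked intervals were discovered in lexicographic k-mer order. Callers
#' must establish membership with [in_right_maximal()] first.
#'
#' @param marks a `kmer_marks` object.
#' @param lb suffix array index.
#' @export
id_right_maximal <- function(marks, lb) {
  (rank1(marks$B_r, lb) + 1L) %/% 2L
}

#' Identifier of a split node
#'
#' For the left boundary `lb` of a non-right-maximal k-mer interval whose
#' right boundary carries a one in `B_l`, the identifier is
#' `rightMax + rank1(B_l, lb - 1) + 1`.
#'
#' @param marks a `kmer_marks` object.
#' @param lb suffix array index (left boundary).
#' @export
id_left_split <- function(marks, lb) {
  marks$rightMax + rank1(marks$B_l, lb - 1L) + 1L
}

#' Build the implicit compressed de Bruijn graph
#'
#' Runs the left-extension construction: seeds the right-maximal k-mer
#' nodes (identifiers `1..rightMax`) and the `d` stop nodes (identifiers
#' `rightMax + leftMax + j`, `j = 1..d`, where `j` is the suffix array
#' index of the terminating `'$'`/`'#'` suffix), then processes a FIFO
#' queue of node identifiers. Each dequeued node is extended leftwards with
#' [get_intervals()]: separator branches are dropped (the node is a start
#' node for those sequences), branches whose `c w` k-prefix is right-maximal
#' stop (a predecessor node ends there), a sole surviving branch of a
#' singleton list extends the node in place, and any other surviving branch
#' creates a split node `(k, i, j - i + 1, i)` with identifier
#' `rightMax + rank1(B_l, i - 1) + 1`.
#'
#' @param fm an `fm_index`.
#' @param marks a `kmer_marks` object for the same index.
#' @param trace if `TRUE`, record every construction event (seeds,
#'   getIntervals calls, rank tests, extensions, splits) in the returned
#'   object's `trace` component. Intended for walkthrough-level inspection
#'   of small inputs.
#' @return object of class `implicit_cdbg`: vectors `len`, `lb`, `size`,
#'   `suffix_lb` indexed by identifier, plus `N`, `rightMax`, `leftMax`,
#'   `d`, `k` (and `trace` when requested).
#' @examples
#' fm <- build_fm_index(encode_and_concatenate(c(x = "ACTACGTACGTACG")))
#' g <- build_implicit(fm, kmer_marks(fm, 3))
#' cbind(g$len, g$lb, g$size, g$suffix_lb)
#' @export
build_implicit <- function(fm, marks, trace = FALSE) {
  stopifnot(inherits(marks, "kmer_marks"))
  k <- marks$k
  d <- fm$text$d
  rightMax <- marks$rightMax
  leftMax <- marks$leftMax
  N <- rightMax + leftMax + d
  len <- integer(N)
  lb <- integer(N)
  size <- integer(N)
  suf <- integer(N)
  created <- logical(N)
  ev <- vector("list", 64L)
  nev <- 0L
  note <- function(e) {
    nev <<- nev + 1L
    ev[[nev]] <<- e
  }
  queue <- integer(N)
  qtail <- 0L
  if (rightMax > 0L) {
    s <- marks$seeds
    ids <- seq_len(rightMax)
    len[ids] <- s[, 1L]
    lb[ids] <- s[, 2L]
    size[ids] <- s[, 3L]
    suf[ids] <- s[, 4L]
    created[ids] <- TRUE
    queue[ids] <- ids
    qtail <- rightMax
    if (trace) {
      for (id in ids) {
        note(list(
          type = "seed", id = id, len = len[id], lb = lb[id],
          size = size[id], suffix_lb = suf[id]
        ))
      }
    }
  }
  for (j in seq_len(d)) {
    id <- rightMax + leftMax + j
    len[id] <- 1L
    lb[id] <- j
    size[id] <- 1L
    suf[id] <- j
    created[id] <- TRUE
    qtail <- qtail + 1L
    queue[qtail] <- id
    if (trace) note(list(type = "stop_seed", id = id, j = j))
  }
  Brbits <- marks$B_r$bits
  Brrk <- marks$B_r$rk
  Blrk <- marks$B_l$rk
  qhead <- 1L
  while (qhead <= qtail) {
    id <- queue[qhead]
    qhead <- qhead + 1L
    clb <- lb[id]
    crb <- clb + size[id] - 1L
    repeat {
      m <- .gi(fm, clb, crb)
      if (trace) {
        note(list(type = "get_intervals", id = id, lb = clb, rb = crb, m = m))
      }
      ext <- FALSE
      nl <- nrow(m)
      for (r in seq_len(nl)) {
        code <- m[[r, 1L]]
        i <- m[[r, 2L]]
        j <- m[[r, 3L]]
        if (code <= 1L) next # separator branch: start of a sequence
        rk <- Brrk[i + 1L] # rank1(B_r, i)
        if (rk %% 2L == 1L || Brbits[i] == 1L) {
          # k-prefix of c*w is right-maximal: a predecessor node ends here
          if (trace) {
            note(list(
              type = "br_stop", id = id, i = i, j = j,
              rank = rk, bit = Brbits[i]
            ))
          }
          next
        }
        if (nl == 1L) {
          # w is not left-maximal: extend the node in place
          lb[id] <- i
          len[id] <- len[id] + 1L
          clb <- i
          crb <- j
          ext <- TRUE
          if (trace) {
            note(list(
              type = "extend", id = id, len = len[id], lb = i,
              rank = rk, bit = Brbits[i]
            ))
          }
        } else {
          # w is left-maximal: split
          newId <- rightMax + Blrk[i] + 1L # rightMax + rank1(B_l, i-1) + 1
          if (trace) {
            note(list(
              type = "split", id = id, i = i, j = j,
              bl_rank = Blrk[i], new_id = newId, fresh = !created[newId]
            ))
          }
          if (!created[newId]) {
            created[newId] <- TRUE
            len[newId] <- k
            lb[newId] <- i
            size[newId] <- j - i + 1L
            suf[newId] <- i
            qtail <- qtail + 1L
            queue[qtail] <- newId
          }
        }
      }
      if (!ext) break
    }
  }
  if (!all(created)) {
    stop(sprintf(
      "pancdbg_internal: %d node identifier(s) never materialized",
      sum(!created)
    ))
  }
  structure(
    list(
      len = len, lb = lb, size = size, suffix_lb = suf,
      N = N, rightMax = rightMax, leftMax = leftMax,
      d = d, k = k,
      trace = if (trace) ev[seq_len(nev)] else NULL
    ),
    class = "implicit_cdbg"
  )
}

#' @export
print.implicit_cdbg <- function(x, ...) {
  cat(sprintf(
    "implicit_cdbg: k = %d, %d node(s) (%d right-maximal, %d split, %d stop)\n",
    x$k, x$N, x$rightMax, x$leftMax, x$d
  ))
  invisible(x)
}

.check_id <- function(G, id) {
  if (length(id) != 1L || is.na(id) || id < 1L || id > G$N) {
    stop("pancdbg_bad_node_id")
  }
}

#' Is a node a stop node?
#' @param G an `implicit_cdbg`.
#' @param id node identifier.
#' @export
is_stop_node <- function(G, id) {
  id > G$rightMax + G$leftMax
}

#' String spelled by a node
#'
#' `S[SA[lb] .. SA[lb] + len - 1]`. Stop node strings end in `'#'` or
#' `'$'`.
#'
#' @param fm an `fm_index`.
#' @param G an `implicit_cdbg`.
#' @param id node identifier.
#' @export
node_string <- function(fm, G, id) {
  .check_id(G, id)
  p <- fm$sa[G$lb[id]]
  substr(fm$text$S, p, p + G$len[id] - 1L)
}

#' Start positions of a node's string in S
#'
#' Sorted 1-based positions, read off the suffix array interval
#' `[lb .. lb + size - 1]`.
#'
#' @inheritParams node_string
#' @export
node_positions <- function(fm, G, id) {
  .check_id(G, id)
  sort(fm$sa[G$lb[id]:(G$lb[id] + G$size[id] - 1L)])
}

#' Summary statistics of a compressed de Bruijn graph
#'
#' @param fm an `fm_index`.
#' @param marks a `kmer_marks` object.
#' @param G an `implicit_cdbg`.
#' @return list with `n_nodes`, `rightMax`, `leftMax`, `d`, `k`,
#'   `n_edges` (every node visit except the terminal visit of a stop node
#'   contributes one edge, so `sum(size) - d`), and `longest_node` (maximal
#'   node string length).
#' @export
cdbg_stats <- function(fm, marks, G) {
  list(
    n_nodes = G$N, rightMax = G$rightMax, leftMax = G$leftMax,
    d = G$d, k = G$k,
    n_edges = sum(G$size) - G$d,
    longest_node = max(G$len)
  )
}
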