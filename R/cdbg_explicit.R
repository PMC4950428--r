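# Conversion of the implicit representation into the explicit one
# (position lists, adjacency lists, start nodes) by one backward walk per
# sequence, starting at the stop node of the last sequence. The index
# shift between a node's k-suffix interval and its full-string interval
# makes each step constant-time.

#' Index shift from a node's k-suffix interval to its full interval
#'
#' If the suffix starting at text position `p` sits at index `i` of the
#' node's k-suffix interval `[suffix_lb .. suffix_lb + size - 1]`, then the
#' suffix starting at `p - (len - k)` (the start of that occurrence of the
#' full node string) sits at index `lb + (i - suffix_lb)` of the node's
#' full interval, i.e. `SA[lb + (i - suffix_lb)] = SA[i] - (len - k)`.
#' For `len = k` this is the identity.
#'
#' @param G an `implicit_cdbg`.
#' @param id node identifier (not a stop node).
#' @param i index within the node's k-suffix interval.
#' @export
suffix_index_shift <- function(G, id, i) {
  .check_id(G, id)
  if (is_stop_node(G, id)) {
    stop("pancdbg_stop_node: index shift is undefined for stop nodes")
  }
  b <- G$suffix_lb[id]
  if (i < b || i > b + G$size[id] - 1L) {
    stop("pancdbg_index_out_of_range: i outside the k-suffix interval")
  }
  G$lb[id] + (i - b)
}

#' Convert the implicit graph to the explicit (splitMEM-style) form
#'
#' Performs `d` backward walks over the text, one per sequence, starting at
#' the stop node of the last sequence (`id = rightMax + leftMax + 1`, whose
#' string ends with `'$'`). Each step prepends the current position to the
#' node's position list, reads the preceding symbol from the BWT, resolves
#' the predecessor node through `B_r`/`B_l`, and prepends the current
#' identifier to the predecessor's adjacency list. A separator symbol ends
#' the walk (the current node is the start node of the sequence) and, for
#' `'#'`, chains into the stop node of the preceding sequence. Because the
#' walks run backwards (sequence d first) and lists are filled back to
#' front, every position list ends up in ascending order and every
#' adjacency list in global visit order without sorting.
#'
#' @param fm an `fm_index`.
#' @param marks a `kmer_marks` object.
#' @param G an `implicit_cdbg` built from the same index and marks.
#' @return object of class `explicit_cdbg`: `len`, `posList` (list of
#'   integer vectors), `adjList` (list of integer vectors; i-th visit of a
#'   node is followed by the i-th entry), `StartNodes` (one identifier per
#'   sequence), plus the identifier bookkeeping of the implicit graph.
#' @export
to_explicit <- function(fm, marks, G) {
  stopifnot(inherits(G, "implicit_cdbg"))
  k <- G$k
  d <- G$d
  n <- fm$n
  rightMax <- G$rightMax
  leftMax <- G$leftMax
  N <- G$N
  stop_first <- rightMax + leftMax + 1L
  posList <- lapply(G$size, integer)
  adjList <- lapply(seq_len(N), function(id) {
    if (id >= stop_first) integer(0L) else integer(G$size[id])
  })
  fillp <- G$size
  filla <- G$size
  StartNodes <- integer(d)
  Brbits <- marks$B_r$bits
  Brrk <- marks$B_r$rk
  Blrk <- marks$B_l$rk
  bwtc <- fm$bwt_codes
  lf <- fm$lf
  Glb <- G$lb
  Gsuf <- G$suffix_lb
  Glen <- G$len
  seqno <- d
  id <- stop_first
  pos <- n - Glen[id] + 1L
  idx <- Glb[id]
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > n + N + 1L) {
      stop("pancdbg_inconsistent_graph: backward walk did not terminate")
    }
    if (is.na(idx) || idx < 1L || idx > n || fillp[id] < 1L) {
      stop("pancdbg_inconsistent_graph: walk left the node's interval")
    }
    posList[[id]][fillp[id]] <- pos
    fillp[id] <- fillp[id] - 1L
    cc <- bwtc[idx]
    if (cc <= 1L) {
      # separator: this node starts sequence seqno
      if (seqno < 1L) stop("pancdbg_inconsistent_graph: too many walks")
      StartNodes[seqno] <- id
      if (cc == 0L) break # '$' precedes position 1: all walks done
      s <- lf[idx] # suffix array index (2..d) of the '#' suffix
      seqno <- seqno - 1L
      id2 <- rightMax + leftMax + s
      pos <- pos - 1L - Glen[id2] + 1L
      idx <- Glb[id2]
      id <- id2
      next
    }
    i <- lf[idx]
    rk <- Brrk[i + 1L]
    if (rk %% 2L == 1L || Brbits[i] == 1L) {
      newId <- (rk + 1L) %/% 2L
    } else {
      newId <- rightMax + Blrk[i] + 1L
    }
    if (newId < 1L || newId >= stop_first || filla[newId] < 1L) {
      stop("pancdbg_inconsistent_graph: predecessor resolution failed")
    }
    adjList[[newId]][filla[newId]] <- id
    filla[newId] <- filla[newId] - 1L
    pos <- pos - 1L - (Glen[newId] - k)
    idx <- Glb[newId] + (i - Gsuf[newId])
    id <- newId
  }
  if (seqno != 1L || any(fillp != 0L)) {
    stop("pancdbg_inconsistent_graph: position lists not fully populated")
  }
  if (any(filla[seq_len(stop_first - 1L)] != 0L)) {
    stop("pancdbg_inconsistent_graph: adjacency lists not fully populated")
  }
  structure(
    list(
      id = seq_len(N), len = Glen, posList = posList, adjList = adjList,
      StartNodes = StartNodes, N = N, d = d, k = k,
      rightMax = rightMax, leftMax = leftMax,
      stop_ids = stop_first:N
    ),
    class = "explicit_cdbg"
  )
}

#' @export
print.explicit_cdbg <- function(x, ...) {
  cat(sprintf(
    "explicit_cdbg: k = %d, %d node(s), %d edge(s), %d sequence walk(s)\n",
    x$k, x$N, sum(lengths(x$adjList)), x$d
  ))
  invisible(x)
}

# internal: replay all d walks through the explicit graph by consuming the
# adjacency lists in global visit order; returns one identifier vector per
# sequence.
.walk_all <- function(explicit) {
  cnt <- integer(explicit$N)
  is_stop <- logical(explicit$N)
  is_stop[explicit$stop_ids] <- TRUE
  lapply(seq_len(explicit$d), function(j) {
    id <- explicit$StartNodes[j]
    ids <- integer(0L)
    guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > sum(lengths(explicit$posList)) + 1L) {
        stop("pancdbg_inconsistent_graph: walk replay did not terminate")
      }
      ids[length(ids) + 1L] <- id
      if (is_stop[id]) break
      cnt[id] <<- cnt[id] + 1L
      nxt <- explicit$adjList[[id]][cnt[id]]
      if (is.na(nxt)) {
        stop("pancdbg_inconsistent_graph: adjacency list exhausted")
      }
      id <- nxt
    }
    ids
  })
}

#' Reconstruct a sequence from the explicit graph
#'
#' Walks sequence `j` from its start node, concatenating node strings with
#' an overlap of `k - 1` symbols. The result is `S^j` followed by its
#' terminator (`'#'`, or `'$'` for the last sequence); it must equal the
#' input, which makes this the canonical round-trip validation.
#'
#' @param explicit an `explicit_cdbg`.
#' @param text the `pan_text` the graph was built from.
#' @param fm the `fm_index`.
#' @param G the `implicit_cdbg`.
#' @param j sequence number in `1..d`.
#' @export
reconstruct_sequence <- function(explicit, text, fm, G, j) {
  stopifnot(j >= 1L, j <= explicit$d)
  walks <- .walk_all(explicit)
  ids <- walks[[j]]
  parts <- vapply(ids, function(id) node_string(fm, G, id), character(1L))
  k <- explicit$k
  paste0(
    parts[1L],
    paste(vapply(parts[-1L], substring, character(1L), first = k), collapse = "")
  )
}
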