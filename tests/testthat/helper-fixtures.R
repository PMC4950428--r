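# Shared fixtures and comparison helpers. All randomness is seeded at the
# call site, so every test file is deterministic.

# the worked example used throughout: single sequence, k = 3
example_build <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_all(c(x = "ACTACGTACGTACG"), 3L)
    }
    cache
  }
})

build_all <- function(seqs, k) {
  tx <- encode_and_concatenate(seqs)
  fm <- build_fm_index(tx)
  mk <- kmer_marks(fm, k)
  G <- build_implicit(fm, mk)
  list(tx = tx, fm = fm, mk = mk, G = G, k = k)
}

rand_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# one random pan-genome case: either independent random sequences or
# near-identical mutated copies; k in 2..5 (clamped below the shortest
# sequence)
rand_case <- function(min_len = 20L, max_len = 200L) {
  d <- sample(1:4, 1L)
  if (stats::runif(1L) < 0.5) {
    lens <- sample(min_len:max_len, d, replace = TRUE)
    seqs <- vapply(lens, rand_seq, character(1L))
  } else {
    cfg <- simulation_config(
      base_length = sample(min_len:max_len, 1L), num_sequences = d,
      substitution_rate = 0.02, indel_rate = 0.005
    )
    seqs <- simulate_pangenome(cfg)
  }
  names(seqs) <- paste0("s", seq_len(d))
  k <- sample(2:5, 1L)
  k <- min(k, min(nchar(seqs)) - 1L)
  list(seqs = seqs, k = max(2L, k))
}

# canonical (string, position-list) representation of a graph, sorted, for
# exact multiset comparison between implementation and oracle
impl_canonical <- function(b) {
  strs <- vapply(
    seq_len(b$G$N), function(id) node_string(b$fm, b$G, id), character(1L)
  )
  poss <- lapply(seq_len(b$G$N), function(id) node_positions(b$fm, b$G, id))
  o <- order(strs, vapply(poss, `[`, integer(1L), 1L), method = "radix")
  list(str = strs[o], pos = lapply(poss[o], as.integer))
}

oracle_canonical <- function(og) {
  o <- order(
    og$node_str, vapply(og$node_pos, `[`, integer(1L), 1L),
    method = "radix"
  )
  list(str = og$node_str[o], pos = lapply(og$node_pos[o], as.integer))
}

# every separator-free substring of S with length in kmin..kmax, mapped to
# its (possibly overlapping) occurrence positions
substr_dict <- function(S, kmin, kmax) {
  n <- nchar(S)
  out <- list()
  for (len in kmin:min(kmax, n)) {
    st <- seq_len(n - len + 1L)
    subs <- substring(S, st, st + len - 1L)
    ok <- !grepl("[#$]", subs)
    out[[length(out) + 1L]] <- split(st[ok], subs[ok])
  }
  do.call(c, out)
}

# per-sequence node-string visit sequences of the explicit graph
impl_walk_strings <- function(b, ex) {
  strs <- vapply(
    seq_len(b$G$N), function(id) node_string(b$fm, b$G, id), character(1L)
  )
  lapply(pancdbg:::.walk_all(ex), function(ids) unname(strs[ids]))
}

oracle_walk_strings <- function(og) {
  lapply(og$walks, function(ix) unname(og$node_str[ix]))
}

# full equivalence check of one fixture against the oracle. Comparisons
# are plain R (a single testthat expectation over thousands of patterns
# would otherwise dominate the runtime); returns a character vector of
# problem descriptions, empty when everything matches.
check_fixture_against_oracle <- function(seqs, k, search_max_len = 12L) {
  bad <- character(0L)
  b <- build_all(seqs, k)
  og <- oracle_compressed_dbg(seqs, k)
  if (!identical(impl_canonical(b), oracle_canonical(og))) {
    bad <- c(bad, "implicit graph differs from oracle compaction")
  }
  ex <- to_explicit(b$fm, b$mk, b$G)
  if (!identical(impl_walk_strings(b, ex), oracle_walk_strings(og))) {
    bad <- c(bad, "explicit walks differ from oracle walks")
  }
  for (j in seq_len(b$tx$d)) {
    want <- substr(
      b$tx$S, b$tx$seq_starts[j],
      b$tx$seq_starts[j] + b$tx$seq_lengths[j]
    )
    if (!identical(reconstruct_sequence(ex, b$tx, b$fm, b$G, j), want)) {
      bad <- c(bad, sprintf("sequence %d does not round-trip", j))
    }
  }
  if (sum(b$G$size * (b$G$len - k + 1L)) !=
    sum(b$tx$seq_lengths + 2L - k)) {
    bad <- c(bad, "window-coverage conservation violated")
  }
  # exhaustive pattern search: every distinct separator-free substring of
  # length k..search_max_len (duplicates would repeat identical queries)
  dict <- substr_dict(b$tx$S, k, search_max_len)
  strs <- vapply(
    seq_len(b$G$N), function(id) node_string(b$fm, b$G, id), character(1L)
  )
  for (p in names(dict)) {
    res <- search_pattern(b$fm, b$mk, b$G, p)
    if (!res$found) {
      bad <- c(bad, sprintf("pattern %s not found", p))
      next
    }
    if (!identical(search_occurrences(b$fm, res), sort(dict[[p]]))) {
      bad <- c(bad, sprintf("pattern %s: wrong occurrence set", p))
    }
    expected_path <- og$node_str[
      pancdbg:::.oracle_pattern_path(og, dict[[p]][1L], nchar(p))
    ]
    if (!identical(unname(strs[res$res_list]), unname(expected_path))) {
      bad <- c(bad, sprintf("pattern %s: wrong node path", p))
    }
  }
  attr(bad, "built") <- list(b = b, og = og, ex = ex, n_patterns = length(dict))
  bad
}

# brute-force B_r / B_l directly from the definitions (distinct separator
# occurrences treated as unique symbols; virtual predecessor before
# position 1)
brute_marks <- function(tx, fm, k) {
  n <- tx$n
  toks <- strsplit(tx$S, "", fixed = TRUE)[[1L]]
  sp <- which(tx$codes == 1L)
  toks[sp] <- paste0("#", seq_along(sp))
  np <- n - k + 1L
  km <- do.call(paste0, lapply(0:(k - 1L), function(o) toks[(1L + o):(np + o)]))
  occ <- split(seq_len(np), km)
  isa <- integer(n)
  isa[fm$sa] <- seq_len(n)
  follower_tok <- toks[-seq_len(k)] # token at position i + k, i in 1..n-k
  preceder_tok <- c("^virtual", toks[seq_len(n - 1L)]) # token at i - 1
  right_max <- vapply(occ, function(ii) {
    ii2 <- ii[ii <= n - k]
    length(ii) >= 2L && length(unique(follower_tok[ii2])) >= 2L
  }, logical(1L))
  left_max <- vapply(occ, function(ii) {
    length(ii) >= 2L && length(unique(preceder_tok[ii])) >= 2L
  }, logical(1L))
  br <- integer(n)
  bl <- integer(n)
  for (u in names(occ)) {
    I <- isa[occ[[u]]]
    if (right_max[[u]]) {
      br[min(I)] <- 1L
      br[max(I)] <- 1L
    } else if (!grepl("[#$]", u)) {
      p <- occ[[u]][1L]
      if (p <= n - k && left_max[[km[p + 1L]]] %||% FALSE) {
        bl[max(I)] <- 1L
      }
    }
  }
  list(br = br, bl = bl)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
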