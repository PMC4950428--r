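test_that("encode_and_concatenate builds S with boundary metadata", {
  tx <- encode_and_concatenate(c(a = "ACG", b = "AAC"))
  expect_identical(tx$S, "ACG#AAC$")
  expect_identical(tx$n, 8L)
  expect_identical(tx$d, 2L)
  expect_identical(tx$seq_starts, c(1L, 5L))
  expect_identical(tx$seq_lengths, c(a = 3L, b = 3L))

  tx1 <- encode_and_concatenate(c(x = "actacgtacgtacg"))
  expect_identical(tx1$S, "ACTACGTACGTACG$") # uppercased
  expect_identical(tx1$n, 15L)
  expect_identical(tx1$d, 1L)

  # alphabet order: $ < # < remaining symbols in byte order
  expect_identical(tx$alphabet[1:2], c("$", "#"))
  expect_identical(tx$alphabet[-(1:2)], c("A", "C", "G"))

  expect_error(encode_and_concatenate(c(a = "AC$G")), "reserved_symbol")
  expect_error(encode_and_concatenate(c(a = "AC#G")), "reserved_symbol")
  expect_error(encode_and_concatenate(character(0)), "empty_input")
  expect_error(encode_and_concatenate(c(a = "ACG", b = "")), "empty_sequence")
})

test_that("FM-index matches printed index structures of the example", {
  b <- example_build()
  fm <- b$fm
  expect_identical(
    fm$sa,
    c(15L, 12L, 8L, 4L, 1L, 13L, 9L, 5L, 2L, 14L, 10L, 6L, 11L, 7L, 3L)
  )
  expect_identical(fm$bwt, "GTTT$AAAACCCGGC")
  expect_identical(lf_map(fm, 5L), 1L)
  expect_identical(lf_map(fm, 1L), 10L)
  expect_identical(psi(fm, 1L), 5L)
  expect_identical(psi(fm, 13L), 2L)
  expect_error(lf_map(fm, 0L), "out_of_range")
  expect_error(psi(fm, 16L), "out_of_range")
})

test_that("suffix array construction agrees with the naive sort oracle", {
  # tiny hand-checkable case first
  tx <- encode_and_concatenate(c(x = "AA"))
  fm <- build_fm_index(tx)
  expect_identical(fm$sa, c(3L, 2L, 1L))
  expect_identical(fm$bwt, "AA$") # BWT[i] = S[SA[i]-1]: A, A, then '$'

  set.seed(101)
  for (rep in 1:200) {
    d <- sample(1:4, 1L)
    seqs <- vapply(
      sample(2:50, d, replace = TRUE), rand_seq, character(1L)
    )
    names(seqs) <- paste0("s", seq_len(d))
    tx <- encode_and_concatenate(seqs)
    fm <- build_fm_index(tx)
    expect_identical(fm$sa, oracle_suffix_sort(tx))
  }
})

test_that("LF and Psi are mutually inverse and wavelet rank is exact", {
  set.seed(102)
  for (rep in 1:10) {
    seqs <- c(a = rand_seq(sample(10:80, 1L)), b = rand_seq(sample(10:80, 1L)))
    fm <- build_fm_index(encode_and_concatenate(seqs))
    n <- fm$n
    expect_identical(fm$psi_v[fm$lf], seq_len(n))
    expect_identical(fm$lf[fm$psi_v], seq_len(n))
    # lf_map (wavelet-tree route) equals the precomputed LF
    expect_identical(vapply(seq_len(n), lf_map, integer(1L), fm = fm), fm$lf)
    # wavelet rank equals direct counting for every symbol / position
    bw <- fm$bwt_codes
    for (cc in 0:(fm$sigma - 1L)) {
      expect_identical(
        vapply(0:n, function(i) wt_rank(fm$wt, cc, i), integer(1L)),
        c(0L, cumsum(bw == cc))
      )
    }
  }
})

test_that("backward search chains locate exactly the naive occurrence sets", {
  set.seed(103)
  for (rep in 1:8) {
    d <- sample(1:2, 1L)
    seqs <- vapply(
      sample(5:30, d, replace = TRUE), rand_seq, character(1L),
      alphabet = c("A", "C", "G")
    )
    names(seqs) <- paste0("s", seq_len(d))
    tx <- encode_and_concatenate(seqs)
    if (tx$n > 64L) next
    fm <- build_fm_index(tx)
    n <- tx$n
    # every substring of S, exhaustively
    for (a in seq_len(n)) {
      for (bb in a:n) {
        w <- substr(tx$S, a, bb)
        iv <- interval(1L, n)
        for (t in nchar(w):1) {
          iv <- backward_search(fm, substr(w, t, t), iv)
        }
        naive <- which(substring(
          tx$S, seq_len(n - nchar(w) + 1L),
          seq_len(n - nchar(w) + 1L) + nchar(w) - 1L
        ) == w)
        if (is_empty_interval(iv)) {
          expect_length(naive, 0L)
        } else {
          expect_identical(sort(fm$sa[iv[1L]:iv[2L]]), naive)
        }
      }
    }
  }
  # absent extension gives the empty interval
  fm <- example_build()$fm
  expect_true(is_empty_interval(backward_search(fm, "A", interval(2, 4))))
  expect_true(is_empty_interval(backward_search(fm, "N", interval(1, 15))))
})

test_that("get_intervals returns all left extensions and partitions input", {
  fm <- example_build()$fm
  expect_identical(
    get_intervals(fm, interval(2, 4)),
    list(list(symbol = "T", lb = 13L, rb = 15L))
  )
  expect_identical(
    get_intervals(fm, interval(13, 15)),
    list(
      list(symbol = "C", lb = 9L, rb = 9L),
      list(symbol = "G", lb = 11L, rb = 12L)
    )
  )
  expect_identical(
    get_intervals(fm, interval(1, 1)),
    list(list(symbol = "G", lb = 10L, rb = 10L))
  )
  expect_error(get_intervals(fm, interval(5, 4)), "empty_interval")

  # partition property on random intervals of random texts
  set.seed(104)
  for (rep in 1:20) {
    fm2 <- build_fm_index(encode_and_concatenate(
      c(a = rand_seq(sample(10:100, 1L)), b = rand_seq(sample(10:100, 1L)))
    ))
    for (q in 1:20) {
      lb <- sample(fm2$n, 1L)
      rb <- lb + sample.int(fm2$n - lb + 1L, 1L) - 1L
      gi <- get_intervals(fm2, interval(lb, rb))
      sizes <- vapply(gi, function(e) e$rb - e$lb + 1L, integer(1L))
      expect_identical(sum(sizes), rb - lb + 1L)
      # disjoint: intervals sorted by lb must not overlap
      lbs <- vapply(gi, `[[`, integer(1L), "lb")
      rbs <- vapply(gi, `[[`, integer(1L), "rb")
      o <- order(lbs)
      expect_true(all(lbs[o][-1L] > rbs[o][-length(o)]))
      # symbols ascend in alphabet order
      syms <- vapply(gi, `[[`, character(1L), "symbol")
      expect_false(is.unsorted(match(syms, fm2$text$alphabet), strictly = TRUE))
    }
  }
})
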