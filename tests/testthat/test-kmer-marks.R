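test_that("LCP level array matches the example's LCP column for k = 3", {
  b <- example_build()
  L <- compute_lcp_levels(b$fm, 3L)
  # LCP = -1,0,3,7,2,0,2,6,1,0,1,5,0,4,8,-1 classified against k = 3
  expect_identical(
    which(L$L == 0L),
    c(1L, 2L, 5L, 6L, 7L, 9L, 10L, 11L, 13L, 16L)
  )
  expect_identical(which(L$L == 1L), 3L)
  expect_identical(which(L$L == 2L), c(4L, 8L, 12L, 14L, 15L))
  expect_error(compute_lcp_levels(b$fm, 1L), "bad_k")
  expect_error(compute_lcp_levels(b$fm, 14L), "bad_k")
})

test_that("full and level-capped LCP agree with the naive oracle", {
  tx <- encode_and_concatenate(c(a = "ACG", b = "AAC"))
  fm <- build_fm_index(tx)
  lv <- lcp_from_bwt(fm)
  expect_identical(lv, oracle_lcp(tx))
  L2 <- compute_lcp_levels(fm, 2L)
  expect_identical(
    L2$L,
    ifelse(lv < 2L, 0L, ifelse(lv == 2L, 1L, 2L))
  )

  set.seed(201)
  for (rep in 1:30) {
    d <- sample(1:4, 1L)
    seqs <- vapply(sample(5:60, d, TRUE), rand_seq, character(1L))
    names(seqs) <- paste0("s", seq_len(d))
    tx <- encode_and_concatenate(seqs)
    fm <- build_fm_index(tx)
    lv <- lcp_from_bwt(fm)
    expect_identical(lv, oracle_lcp(tx))
    k <- min(sample(2:5, 1L), min(nchar(seqs)) - 1L)
    if (k < 2L) next
    expect_identical(
      compute_lcp_levels(fm, k)$L,
      ifelse(lv < k, 0L, ifelse(lv == k, 1L, 2L))
    )
  }
})

test_that("degenerate text without length-k repeats marks nothing", {
  fm <- build_fm_index(encode_and_concatenate(c(x = "ACGTN")))
  mk <- kmer_marks(fm, 2L)
  expect_identical(mk$rightMax, 0L)
  expect_identical(mk$leftMax, 0L)
  expect_identical(sum(mk$B_r$bits), 0L)
  expect_identical(sum(mk$B_l$bits), 0L)
})

test_that("B_r and B_l reproduce the example and seed the right node", {
  b <- example_build()
  mk <- b$mk
  expect_identical(which(mk$B_r$bits == 1L), c(2L, 4L))
  expect_identical(mk$rightMax, 1L)
  expect_identical(
    mk$seeds,
    cbind(len = 3L, lb = 2L, size = 3L, suffix_lb = 2L)
  )
  expect_identical(which(mk$B_l$bits == 1L), c(9L, 12L))
  expect_identical(mk$leftMax, 2L)
})

test_that("marks equal the brute-force definitional sets on random texts", {
  set.seed(202)
  for (rep in 1:60) {
    d <- sample(1:4, 1L)
    if (rep %% 2L == 0L) {
      seqs <- vapply(sample(8:60, d, TRUE), rand_seq, character(1L))
    } else {
      seqs <- simulate_pangenome(simulation_config(
        base_length = sample(10:50, 1L), num_sequences = d,
        substitution_rate = 0.05, indel_rate = 0.01
      ))
    }
    names(seqs) <- paste0("s", seq_len(d))
    k <- max(2L, min(sample(2:5, 1L), min(nchar(seqs)) - 1L))
    b <- build_all(seqs, k)
    ref <- brute_marks(b$tx, b$fm, k)
    expect_identical(b$mk$B_r$bits, ref$br)
    expect_identical(b$mk$B_l$bits, ref$bl)

    # invariants: B_r ones pair into disjoint intervals
    expect_identical(sum(b$mk$B_r$bits) %% 2L, 0L)
    expect_identical(sum(b$mk$B_r$bits), 2L * b$mk$rightMax)
    expect_identical(sum(b$mk$B_l$bits), b$mk$leftMax)
    # clearing: no B_l one inside a right-maximal interval
    ones <- which(b$mk$B_l$bits == 1L)
    if (length(ones)) {
      expect_false(any(vapply(
        ones, function(p) in_right_maximal(b$mk, interval(p, p)),
        logical(1L)
      )))
    }
    # separator isolation: marked k-mers are separator-free
    marked <- which(b$mk$B_r$bits == 1L | b$mk$B_l$bits == 1L)
    if (length(marked)) {
      kmers <- substring(b$tx$S, b$fm$sa[marked], b$fm$sa[marked] + k - 1L)
      expect_false(any(grepl("[#$]", kmers)))
    }
  }
})

test_that("mark_bl on 'ACGTT#ACGCC' matches the definitional oracle", {
  b <- build_all(c(a = "ACGTT", b = "ACGCC"), 3L)
  ref <- brute_marks(b$tx, b$fm, 3L)
  # ACG is the only right-maximal 3-mer; its interval boundaries are marked
  acg <- backward_search(
    b$fm, "A", backward_search(b$fm, "C", backward_search(
      b$fm, "G", interval(1L, b$fm$n)
    ))
  )
  want <- integer(b$fm$n)
  want[c(acg[[1L]], acg[[2L]])] <- 1L
  expect_identical(b$mk$B_r$bits, want)
  expect_identical(b$mk$B_r$bits, ref$br)
  expect_identical(b$mk$B_l$bits, ref$bl)
})
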