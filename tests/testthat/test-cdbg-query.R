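test_that("document array follows the ownership rule", {
  b <- example_build()
  doc <- build_document_array(b$fm)
  expect_identical(doc$D, rep(1L, 15L))

  b2 <- build_all(c(a = "ACGTT", b = "ACGCC"), 3L)
  doc2 <- build_document_array(b2$fm)
  expect_identical(doc2$D, ifelse(b2$fm$sa <= 6L, 1L, 2L))

  # d identical sequences: per-sequence counts are equal for every interval
  b3 <- build_all(c(a = "ACGTACG", b = "ACGTACG", c = "ACGTACG"), 3L)
  doc3 <- build_document_array(b3$fm)
  iv <- backward_search(b3$fm, "A", backward_search(
    b3$fm, "C", backward_search(b3$fm, "G", interval(1L, b3$fm$n))
  ))
  # interval of "GCA"? no - chain applied right-to-left gives "ACG"
  sq <- interval_sequences(doc3, iv)
  expect_identical(sq$seq, 1:3)
  expect_true(all(sq$count == sq$count[1L]))
})

test_that("interval and node membership queries count occurrences", {
  b <- example_build()
  doc <- build_document_array(b$fm)
  expect_identical(
    interval_sequences(doc, interval(13L, 15L)),
    data.frame(seq = 1L, count = 3L)
  )
  expect_identical(nrow(interval_sequences(doc, interval(2L, 1L))), 0L)
  expect_identical(
    node_sequences(doc, b$G, 1L),
    data.frame(seq = 1L, count = 3L)
  )
  expect_identical(
    node_sequences(doc, b$G, 2L),
    data.frame(seq = 1L, count = 1L)
  )

  b2 <- build_all(c(a = "ACGTT", b = "ACGCC"), 3L)
  doc2 <- build_document_array(b2$fm)
  shared <- which(vapply(
    seq_len(b2$G$N), function(id) node_string(b2$fm, b2$G, id) == "ACG",
    logical(1L)
  ))
  expect_identical(
    node_sequences(doc2, b2$G, shared),
    data.frame(seq = 1:2, count = c(1L, 1L))
  )
  gcc <- backward_search(b2$fm, "G", backward_search(
    b2$fm, "C", backward_search(b2$fm, "C", interval(1L, b2$fm$n))
  ))
  # chain right-to-left spells "GCC"
  expect_identical(
    interval_sequences(doc2, gcc),
    data.frame(seq = 2L, count = 1L)
  )
})

test_that("locate_node_of_interval resolves all three marker kinds", {
  b <- example_build()
  expect_identical(
    locate_node_of_interval(b$fm, b$mk, b$G, interval(2L, 4L)),
    list(id = 1L, ell = 0L)
  )
  # TAC-interval [13..15]: one Psi step onto [2..4]
  expect_identical(
    locate_node_of_interval(b$fm, b$mk, b$G, interval(13L, 15L)),
    list(id = 1L, ell = 1L)
  )
  # GTA-interval [11..12]: B_l[12] = 1
  expect_identical(
    locate_node_of_interval(b$fm, b$mk, b$G, interval(11L, 12L)),
    list(id = 3L, ell = 0L)
  )
  expect_error(
    locate_node_of_interval(b$fm, b$mk, b$G, interval(3L, 2L)),
    "empty_interval"
  )
})

test_that("search reproduces the worked example paths and rejects bad input", {
  b <- example_build()
  res <- search_pattern(b$fm, b$mk, b$G, "ACGTACG")
  expect_true(res$found)
  expect_identical(res$res_list, c(1L, 3L, 1L))
  expect_identical(unname(res$interval), c(3L, 4L))
  expect_identical(search_occurrences(b$fm, res), c(4L, 8L))

  expect_identical(search_pattern(b$fm, b$mk, b$G, "ACG")$res_list, 1L)
  expect_false(search_pattern(b$fm, b$mk, b$G, "AAA")$found)
  expect_false(search_pattern(b$fm, b$mk, b$G, "NGT")$found) # N not in S
  expect_error(search_pattern(b$fm, b$mk, b$G, "AC"), "too_short")
  expect_error(search_pattern(b$fm, b$mk, b$G, "AC#G"), "reserved")
})

test_that("a de Bruijn sequence collapses to one node and is searchable", {
  # order-2 de Bruijn sequence over ACGT: one node, the sequence itself
  b <- build_all(c(x = "AACAGATCCGCTGGTT"), 2L)
  expect_identical(b$G$N, 1L)
  expect_identical(node_string(b$fm, b$G, 1L), "AACAGATCCGCTGGTT$")
  res <- search_pattern(b$fm, b$mk, b$G, "CCGC")
  expect_identical(res$res_list, 1L)
  expect_identical(search_occurrences(b$fm, res), 8L)
})

test_that("membership counts match naive per-sequence substring counts", {
  set.seed(501)
  for (rep in 1:8) {
    cs <- rand_case(max_len = 80L)
    b <- build_all(cs$seqs, cs$k)
    doc <- build_document_array(b$fm)
    dict <- substr_dict(b$tx$S, cs$k, 8L)
    pats <- sample(names(dict), min(40L, length(dict)))
    for (p in pats) {
      res <- search_pattern(b$fm, b$mk, b$G, p)
      got <- interval_sequences(doc, res$interval)
      naive <- table(findInterval(dict[[p]], b$tx$seq_starts))
      expect_identical(got$seq, as.integer(names(naive)))
      expect_identical(got$count, as.integer(naive))
      # locate cost bound: offset stays within the first node's string
      expect_true(res$offset >= 0L)
      expect_true(res$offset <= b$G$len[res$res_list[1L]] - cs$k)
    }
    # mutated probes that do not occur return empty results
    for (q in 1:10) {
      p <- sample(names(dict), 1L)
      probe <- paste0(p, paste(
        sample(c("A", "C", "G", "T"), 3L, TRUE),
        collapse = ""
      ))
      if (is.null(dict[[probe]]) && !grepl(probe, b$tx$S, fixed = TRUE)) {
        expect_false(search_pattern(b$fm, b$mk, b$G, probe)$found)
      }
    }
  }
})
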