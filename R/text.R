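#' Concatenate sequences into a pan-genome text
#'
#' Builds the concatenated text `S = S1#S2#...#Sd$` over which all index
#' structures of this package are defined. The `d` input sequences are
#' uppercased and joined with the separator symbol `#`; the sentinel `$` is
#' appended at the end. `$` is the smallest symbol of the ordered alphabet
#' and `#` the second smallest; all remaining symbols follow in ascending
#' byte order. Neither `$` nor `#` may occur inside an input sequence.
#'
#' @param sequences named character vector (or list coercible to one) of
#'   non-empty sequences, one per genome, in the order in which they should
#'   appear in the concatenation.
#' @return an object of class `pan_text` with components `S` (the
#'   concatenated string), `codes` (integer alphabet codes of `S`, `$` = 0,
#'   `#` = 1), `n`, `d`, `seq_names`, `seq_lengths`, `seq_starts` (1-based
#'   start of each sequence in `S`) and `alphabet` (symbols in code order).
#' @examples
#' tx <- encode_and_concatenate(c(a = "ACG", b = "AAC"))
#' tx$S # "ACG#AAC$"
#' @export
encode_and_concatenate <- function(sequences) {
  sequences <- unlist(sequences, use.names = TRUE)
  if (length(sequences) == 0L) {
    stop("pancdbg_empty_input: need at least one sequence")
  }
  if (!is.character(sequences)) {
    stop("pancdbg_bad_input: sequences must be character")
  }
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0L)) {
    stop("pancdbg_empty_sequence: all sequences must be non-empty")
  }
  if (any(grepl("[$#]", sequences))) {
    stop("pancdbg_reserved_symbol: sequences must not contain '$' or '#'")
  }
  nm <- names(sequences)
  if (is.null(nm)) nm <- paste0("seq", seq_along(sequences))
  d <- length(sequences)
  lens <- nchar(sequences)
  S <- paste0(paste(sequences, collapse = "#"), "$")
  n <- nchar(S)
  stopifnot(n == sum(lens) + d)
  chars <- strsplit(S, "", fixed = TRUE)[[1L]]
  plain <- sort(unique(chars[chars != "$" & chars != "#"]), method = "radix")
  # '#' keeps code 1 even for d = 1 (no occurrences), so separator tests
  # are uniformly "code <= 1"
  alphabet <- c("$", "#", plain)
  codes <- match(chars, alphabet) - 1L
  structure(
    list(
      S = S, codes = codes, n = n, d = d,
      seq_names = nm, seq_lengths = lens,
      seq_starts = unname(cumsum(c(1L, lens[-d] + 1L))),
      alphabet = alphabet, sigma = length(alphabet)
    ),
    class = "pan_text"
  )
}

#' @export
print.pan_text <- function(x, ...) {
  cat(sprintf(
    "pan_text: %d sequence(s), total length n = %d, alphabet size %d\n",
    x$d, x$n, x$sigma
  ))
  invisible(x)
}

# internal: which input sequence owns text position p (terminators belong to
# the sequence they end; '$' belongs to the last sequence)
.seq_of_position <- function(text, p) {
  findInterval(p, text$seq_starts)
}
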