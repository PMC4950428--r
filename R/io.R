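# FASTA input, the versioned text container for index + graph, and graph
# exports (TSV mirroring the implicit and explicit tables, DOT, GFA1).

#' Read sequences from a FASTA file
#'
#' Records are returned in file order, uppercased, with all whitespace
#' stripped from the sequence lines. Parsing is delegated to
#' `Biostrings::readBStringSet()` (arbitrary byte alphabet).
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop(sprintf("pancdbg_fasta_error: %s: %s", path, conditionMessage(e)))
    }
  )
  if (length(x) == 0L) {
    stop(sprintf("pancdbg_fasta_error: %s: no records", path))
  }
  seqs <- toupper(gsub("[ \t\r\n]", "", as.character(x)))
  empty <- which(nchar(seqs) == 0L)
  if (length(empty)) {
    stop(sprintf(
      "pancdbg_fasta_error: %s: empty sequence in record %d (%s)",
      path, empty[1L], names(x)[empty[1L]]
    ))
  }
  nm <- sub("\\s.*$", "", names(x))
  stats::setNames(seqs, nm)
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path)
  invisible(path)
}

#' Save index (and optionally graph) to a versioned container
#'
#' A plain-text JSON container holding the sequences, the suffix array,
#' the BWT and - when a graph is included - `k`, the `B_r`/`B_l` bit
#' vectors and the node table. All derived structures (wavelet trees, rank
#' blocks, `LF`/`Psi`) are rebuilt deterministically on load, and the
#' stored suffix array is checked against the rebuilt one, so a round trip
#' reproduces bit-identical query results.
#'
#' @param path output path.
#' @param fm an `fm_index`.
#' @param marks optional [kmer_marks].
#' @param graph optional `implicit_cdbg` (requires `marks`).
#' @export
save_container <- function(path, fm, marks = NULL, graph = NULL) {
  stopifnot(inherits(fm, "fm_index"))
  if (!is.null(graph) && is.null(marks)) {
    stop("pancdbg_bad_container: a graph needs its marks")
  }
  tx <- fm$text
  obj <- list(
    format = "pancdbg-container", version = 1L,
    seq_names = tx$seq_names,
    sequences = strsplit(substr(tx$S, 1L, tx$n - 1L), "#", fixed = TRUE)[[1L]],
    sa = fm$sa, bwt = fm$bwt
  )
  if (!is.null(marks)) {
    obj$k <- marks$k
    obj$rightMax <- marks$rightMax
    obj$leftMax <- marks$leftMax
    obj$br_bits <- paste(marks$B_r$bits, collapse = "")
    obj$bl_bits <- paste(marks$B_l$bits, collapse = "")
  }
  if (!is.null(graph)) {
    obj$graph <- list(
      len = graph$len, lb = graph$lb, size = graph$size,
      suffix_lb = graph$suffix_lb, N = graph$N, d = graph$d
    )
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a container written by [save_container()]
#'
#' @param path container path.
#' @return list with `text`, `fm`, and (when present) `marks` and `graph`.
#' @export
load_container <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pancdbg-container")) {
    stop("pancdbg_bad_container: unrecognized format")
  }
  if (!identical(as.integer(obj$version), 1L)) {
    stop("pancdbg_bad_container: unsupported version")
  }
  text <- encode_and_concatenate(stats::setNames(obj$sequences, obj$seq_names))
  fm <- build_fm_index(text)
  if (!identical(fm$sa, as.integer(obj$sa)) || !identical(fm$bwt, obj$bwt)) {
    stop("pancdbg_bad_container: stored SA/BWT do not match the sequences")
  }
  out <- list(text = text, fm = fm)
  if (!is.null(obj$k)) {
    bits_of <- function(s) as.integer(strsplit(s, "", fixed = TRUE)[[1L]])
    out$marks <- structure(
      list(
        B_r = rank_bits(bits_of(obj$br_bits)),
        B_l = rank_bits(bits_of(obj$bl_bits)),
        rightMax = as.integer(obj$rightMax),
        leftMax = as.integer(obj$leftMax),
        k = as.integer(obj$k), seeds = NULL, L = NULL
      ),
      class = "kmer_marks"
    )
  }
  if (!is.null(obj$graph)) {
    g <- obj$graph
    out$graph <- structure(
      list(
        len = as.integer(g$len), lb = as.integer(g$lb),
        size = as.integer(g$size), suffix_lb = as.integer(g$suffix_lb),
        N = as.integer(g$N), rightMax = out$marks$rightMax,
        leftMax = out$marks$leftMax, d = as.integer(g$d),
        k = out$marks$k, trace = NULL
      ),
      class = "implicit_cdbg"
    )
  }
  out
}

#' Export the implicit node table as TSV
#'
#' One row per node: `id, len, lb, size, suffix_lb`; header metadata
#' (`k`, `d`, `rightMax`, `leftMax`) as leading comment lines.
#'
#' @param G an `implicit_cdbg`.
#' @param path output path.
#' @export
export_implicit_tsv <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# pancdbg implicit graph\tk=%d\td=%d\trightMax=%d\tleftMax=%d",
    G$k, G$d, G$rightMax, G$leftMax
  ), con)
  writeLines("id\tlen\tlb\tsize\tsuffix_lb", con)
  writeLines(sprintf(
    "%d\t%d\t%d\t%d\t%d",
    seq_len(G$N), G$len, G$lb, G$size, G$suffix_lb
  ), con)
  invisible(path)
}

#' Export the explicit graph as TSV
#'
#' One row per node: `id, len, posList, adjList` (comma-separated lists),
#' plus a trailing comment line with the start nodes.
#'
#' @param explicit an `explicit_cdbg`.
#' @param path output path.
#' @export
export_explicit_tsv <- function(explicit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# pancdbg explicit graph\tk=%d\td=%d", explicit$k, explicit$d
  ), con)
  writeLines("id\tlen\tposList\tadjList", con)
  writeLines(vapply(seq_len(explicit$N), function(id) {
    sprintf(
      "%d\t%d\t%s\t%s", id, explicit$len[id],
      paste(explicit$posList[[id]], collapse = ","),
      paste(explicit$adjList[[id]], collapse = ",")
    )
  }, character(1L)), con)
  writeLines(sprintf(
    "# StartNodes\t%s", paste(explicit$StartNodes, collapse = ",")
  ), con)
  invisible(path)
}

#' Export the explicit graph as DOT
#'
#' Node labels are `id:len`; one edge line per adjacency entry, so
#' multi-edges are preserved.
#'
#' @param explicit an `explicit_cdbg`.
#' @param path output path.
#' @export
export_dot <- function(explicit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("digraph cdbg {", con)
  writeLines(sprintf(
    "  n%d [label=\"%d:%d\"];", seq_len(explicit$N),
    seq_len(explicit$N), explicit$len
  ), con)
  for (id in seq_len(explicit$N)) {
    adj <- explicit$adjList[[id]]
    if (length(adj)) {
      writeLines(sprintf("  n%d -> n%d;", id, adj), con)
    }
  }
  writeLines("}", con)
  invisible(path)
}

#' Export the explicit graph as GFA1
#'
#' S-lines carry the node strings; terminator symbols of stop nodes are
#' stripped from the sequence field and recorded in an `XT:Z:` tag.
#' L-lines carry one record per adjacency entry with overlap `(k-1)M`.
#'
#' @param explicit an `explicit_cdbg`.
#' @param fm the `fm_index`.
#' @param G the `implicit_cdbg`.
#' @param path output path.
#' @export
export_gfa <- function(explicit, fm, G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  for (id in seq_len(explicit$N)) {
    s <- node_string(fm, G, id)
    if (id %in% explicit$stop_ids) {
      term <- substr(s, nchar(s), nchar(s))
      body <- substr(s, 1L, nchar(s) - 1L)
      if (nchar(body) == 0L) body <- "*"
      writeLines(sprintf("S\t%d\t%s\tXT:Z:%s", id, body, term), con)
    } else {
      writeLines(sprintf("S\t%d\t%s", id, s), con)
    }
  }
  ov <- sprintf("%dM", explicit$k - 1L)
  for (id in seq_len(explicit$N)) {
    adj <- explicit$adjList[[id]]
    if (length(adj)) {
      writeLines(sprintf("L\t%d\t+\t%d\t+\t%s", id, adj, ov), con)
    }
  }
  invisible(path)
}
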