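# Synthetic pan-genome generation: d near-identical copies of one base
# sequence with point substitutions and short indels, emulating multiple
# genomes of the same or closely related species.

#' Simulation configuration
#'
#' Defaults describe a small bacterial-style toy pan-genome: a few
#' kilobases, a handful of strains, about 1% point divergence and an order
#' of magnitude fewer indels (geometric lengths, mean 2).
#'
#' @param base_length length of the shared base sequence.
#' @param num_sequences number of sequences `d` (base plus `d - 1` mutated
#'   copies).
#' @param substitution_rate per-base substitution probability in `[0, 1)`.
#' @param indel_rate per-base probability of starting an indel in `[0, 1)`.
#' @param seed optional RNG seed; identical seeds give identical FASTA.
#' @param alphabet symbols to draw from.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(base_length = 1000L, num_sequences = 3L,
                              substitution_rate = 0.01, indel_rate = 0.001,
                              seed = NULL, alphabet = c("A", "C", "G", "T")) {
  stopifnot(
    base_length >= 1L, num_sequences >= 1L,
    substitution_rate >= 0, substitution_rate < 1,
    indel_rate >= 0, indel_rate < 1, length(alphabet) >= 2L
  )
  structure(
    list(
      base_length = as.integer(base_length),
      num_sequences = as.integer(num_sequences),
      substitution_rate = substitution_rate,
      indel_rate = indel_rate,
      seed = seed, alphabet = alphabet
    ),
    class = "sim_config"
  )
}

#' Simulate a pan-genome
#'
#' Draws one base sequence uniformly over the alphabet, then derives
#' `d - 1` copies by per-base substitution (to a uniformly chosen
#' different symbol) and indels (insertion or deletion with equal
#' probability, length `1 + Geometric(1/2)`). With all rates zero the
#' copies are identical; the output is deterministic under `seed`.
#'
#' @param cfg a [simulation_config()].
#' @return named character vector of `d` sequences.
#' @export
simulate_pangenome <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    )
    set.seed(cfg$seed)
  }
  ab <- cfg$alphabet
  base <- sample(ab, cfg$base_length, replace = TRUE)
  out <- vector("list", cfg$num_sequences)
  out[[1L]] <- base
  for (j in seq_len(cfg$num_sequences - 1L)) {
    s <- base
    if (cfg$substitution_rate > 0) {
      hit <- which(stats::runif(length(s)) < cfg$substitution_rate)
      for (p in hit) {
        s[p] <- sample(setdiff(ab, s[p]), 1L)
      }
    }
    if (cfg$indel_rate > 0) {
      hit <- which(stats::runif(length(s)) < cfg$indel_rate)
      # apply right to left so earlier positions stay valid
      for (p in rev(hit)) {
        ilen <- 1L + stats::rgeom(1L, 0.5)
        if (stats::runif(1L) < 0.5) {
          s <- append(s, sample(ab, ilen, replace = TRUE), after = p)
        } else {
          drop <- p:min(p + ilen - 1L, length(s))
          if (length(drop) < length(s)) s <- s[-drop]
        }
      }
    }
    out[[j + 1L]] <- s
  }
  stats::setNames(
    vapply(out, paste, character(1L), collapse = ""),
    paste0("seq", seq_len(cfg$num_sequences))
  )
}
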