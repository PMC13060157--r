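#' Reverse complement of DNA strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()] for plain character
#' vectors.
#'
#' @param x character vector of DNA sequences (alphabet `A,C,G,T,N`).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `expr` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

check_dna <- function(x, name = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("`%s` contains characters outside {A,C,G,T,N}", name),
         call. = FALSE)
  }
  if (any(!nzchar(x))) stop(sprintf("`%s` must be nonempty", name), call. = FALSE)
  invisible(x)
}

#' Generate a random genome
#'
#' Uniform-composition random chromosome sequences, used as the substrate for
#' the read simulator.
#'
#' @param lengths named integer vector of chromosome lengths.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return named character vector of chromosome sequences.
#' @export
random_genome <- function(lengths, seed = NULL) {
  stopifnot(length(lengths) > 0, !is.null(names(lengths)))
  with_seed(seed, {
    vapply(lengths, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, character(1))
  })
}
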