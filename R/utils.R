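#' @useDynLib plastrophy, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim pchisq pbinom rnorm runif rbinom setNames dist
#' @importFrom utils read.table write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so that seeded generators never disturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  force(code)
}

## Derive a per-stage child seed from a top-level seed; keeps all stage
## streams distinct but reproducible, and below .Machine$integer.max.
child_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587) + 1L
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

dna_complement <- function(s) chartr("ACGTN", "TGCAN", s)

dna_reverse <- function(s) {
  vapply(s, function(x) intToUtf8(rev(utf8ToInt(x))), character(1), USE.NAMES = FALSE)
}

dna_revcomp <- function(s) {
  if (length(s) == 0) return(s)
  ## Biostrings' C path wins for vectors or long sequences
  if (length(s) > 20 || max(nchar(s)) > 5000) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  } else {
    dna_reverse(dna_complement(s))
  }
}

#' Extract a (possibly origin-wrapping) interval from a circular sequence
#'
#' Coordinates are 0-based half-open; `end` may exceed the sequence length by
#' up to `nchar(seq)` to denote wrap across the origin.
#' @keywords internal
extract_circular <- function(seq, start, end) {
  n <- nchar(seq)
  stopifnot(start >= 0, start < n, end > start, end - start <= n)
  if (end <= n) {
    substr(seq, start + 1L, end)
  } else {
    paste0(substr(seq, start + 1L, n), substr(seq, 1L, end - n))
  }
}

## Rotate a circular sequence so that 0-based position `origin` becomes 0.
rotate_seq <- function(seq, origin) {
  n <- nchar(seq)
  origin <- origin %% n
  if (origin == 0) return(seq)
  paste0(substr(seq, origin + 1L, n), substr(seq, 1L, origin))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
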