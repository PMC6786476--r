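## Dispersed-repeat census in the four orientation classes (forward, reverse,
## complement, inverted) with mismatch tolerance, plus perfect tandem arrays.
## Parameter defaults mirror the classical plastome repeat screen: minimum
## length 20 bp, Hamming distance 3, e-value <= 1e-3 for dispersed repeats;
## minimum total 10 bp and unit lengths 2-50 for perfect tandem repeats.

#' The four dispersed-repeat orientation classes
#' @format Character vector: forward, reverse, complement, inverted.
#' @export
REPEAT_CLASSES <- c("forward", "reverse", "complement", "inverted")

transform_for_class <- function(seq, class) {
  switch(class,
         forward = seq,
         reverse = dna_reverse(seq),
         complement = dna_complement(seq),
         inverted = dna_revcomp(seq),
         stop("unknown repeat class: ", class))
}

## Map a start in transformed coordinates back to genome coordinates.
map_t_interval <- function(start_t, len, n, class) {
  if (class %in% c("forward", "complement")) {
    start_t
  } else {
    (n - start_t - len) %% n
  }
}

## Intersection length of two circular arcs (start, len) on a circle of n.
arc_intersect_len <- function(s1, l1, s2, l2, n) {
  if (l1 == n) return(l2)
  if (l2 == n) return(l1)
  tot <- 0L
  for (shift in c(-n, 0L, n)) {
    tot <- tot + max(0L, min(s1 + l1, s2 + shift + l2) - max(s1, s2 + shift))
  }
  tot
}

#' Expected number of chance repeat pairs of a given length
#'
#' E-value for a repeat of length `l` with `k` mismatches on a genome of
#' `n` bp: the number of candidate position pairs (4 n^2, covering both
#' orientations of the four classes) times the binomial tail probability of
#' at least `l - k` base matches in `l` trials at p = 1/4.
#'
#' @param length repeat length (bp).
#' @param mismatches Hamming distance of the pair.
#' @param genome_len genome length (bp).
#' @return numeric e-value (vectorized).
#' @export
repeat_evalue <- function(length, mismatches, genome_len) {
  stopifnot(all(length >= 1), all(mismatches >= 0))
  tail_p <- stats::pbinom(length - mismatches - 1, size = length, prob = 0.25,
                          lower.tail = FALSE)
  4 * as.numeric(genome_len)^2 * tail_p
}

#' Find maximal dispersed repeats
#'
#' Enumerates maximal repeat pairs on a circular sequence in up to four
#' orientation classes: forward (direct), reverse, complement, and inverted
#' (reverse complement). A pair is maximal when it cannot be extended in
#' either direction without exceeding `max_mismatch` substitutions. Pairs
#' are found by exact-seed anchoring with pigeonhole seeds of length
#' `floor(min_len / (max_mismatch + 1))` (capped at 31) and mismatch-bounded
#' extension. Each unordered pair is reported once; self-identical pairs and
#' pairs whose intervals overlap by more than half the shorter interval are
#' suppressed (tandem arrays are the tandem scanner's job).
#'
#' @param x a [plastome] or DNA string (treated as circular).
#' @param min_len minimum repeat length (bp); must be at least
#'   `2 * (max_mismatch + 1)` so that exact seeding is possible.
#' @param max_mismatch maximum Hamming distance within a pair.
#' @param max_evalue report only pairs with e-value at or below this bound
#'   (`Inf` to disable).
#' @param classes subset of `c("forward","reverse","complement","inverted")`.
#' @return data frame with columns `class`, `start_a`, `start_b` (0-based),
#'   `length`, `mismatches`, `e_value`, sorted by decreasing length.
#' @export
find_maximal_repeats <- function(x, min_len = 20L, max_mismatch = 3L,
                                 max_evalue = 1e-3,
                                 classes = REPEAT_CLASSES) {
  seq <- if (inherits(x, "plastome")) x$sequence else x
  stopifnot(all(classes %in% REPEAT_CLASSES))
  if (min_len < 2 * (max_mismatch + 1)) {
    stop("min_len must be >= 2 * (max_mismatch + 1) for exact seeding")
  }
  n <- nchar(seq)
  seed_len <- min(31L, max(2L, min_len %/% (max_mismatch + 1L)))
  out <- list()
  for (cl in classes) {
    tr <- transform_for_class(seq, cl)
    w <- .find_repeat_windows_cpp(seq, tr, as.integer(min_len),
                                  as.integer(max_mismatch),
                                  as.integer(seed_len))
    if (nrow(w) == 0) next
    start_a <- w[, "start_a"]
    start_b <- map_t_interval(w[, "start_t"], w[, "length"], n, cl)
    len <- w[, "length"]; mism <- w[, "mismatches"]
    ## self-identical pairs
    keep <- !(start_a == start_b)
    ## canonical unordered pair ordering
    swap <- start_b < start_a | (start_b == start_a & FALSE)
    s1 <- ifelse(swap, start_b, start_a)
    s2 <- ifelse(swap, start_a, start_b)
    df <- data.frame(class = cl, start_a = s1, start_b = s2, length = len,
                     mismatches = mism, stringsAsFactors = FALSE)[keep, ]
    df <- df[!duplicated(df[, c("start_a", "start_b", "length")]), ,
             drop = FALSE]
    if (nrow(df) > 0) {
      ov <- mapply(arc_intersect_len, df$start_a, df$length, df$start_b,
                   df$length, MoreArgs = list(n = n))
      df <- df[ov <= 0.5 * df$length, , drop = FALSE]
    }
    out[[cl]] <- df
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(class = character(), start_a = integer(), start_b = integer(),
               length = integer(), mismatches = integer(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res$e_value <- if (nrow(res)) repeat_evalue(res$length, res$mismatches, n)
                 else numeric(0)
  res <- res[res$e_value <= max_evalue, , drop = FALSE]
  res[order(-res$length, res$start_a), , drop = FALSE]
}

#' Find perfect tandem repeats
#'
#' Scans a circular sequence for maximal perfect tandem arrays with unit
#' lengths in `unit_range`, at least two full copies, total length at least
#' `min_total`, and a primitive repeat unit (an array is reported at its
#' smallest unit: `ACACAC` is unit `AC`, never `ACAC`). Homopolymer runs
#' (unit length 1) are outside the unit range and never reported.
#'
#' @param x a [plastome] or DNA string (treated as circular).
#' @param min_total minimum total array length (bp).
#' @param unit_range `c(min, max)` repeat-unit lengths (bp).
#' @return data frame `start` (0-based), `unit_len`, `total`, `copy_number`
#'   (possibly fractional), `unit`.
#' @export
find_tandem_repeats <- function(x, min_total = 10L, unit_range = c(2L, 50L)) {
  seq <- if (inherits(x, "plastome")) x$sequence else x
  m <- .find_tandem_cpp(seq, as.integer(min_total),
                        as.integer(unit_range[1]), as.integer(unit_range[2]))
  if (nrow(m) == 0) {
    return(data.frame(start = integer(), unit_len = integer(),
                      total = integer(), copy_number = numeric(),
                      unit = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(start = m[, "start"], unit_len = m[, "unit_len"],
                   total = m[, "total"], stringsAsFactors = FALSE)
  df$copy_number <- df$total / df$unit_len
  doubled <- paste0(seq, seq)
  df$unit <- substring(doubled, df$start + 1L, df$start + df$unit_len)
  df[order(df$start, df$unit_len), , drop = FALSE]
}

#' Repeat density summaries
#'
#' @param hits data frame of repeat hits (dispersed and/or tandem) carrying
#'   interval columns; dispersed hits contribute both intervals.
#' @param genome_len genome length (bp).
#' @return list with `count_density` (hits per kb) and `bp_fraction`
#'   (fraction of genomic bases covered by at least one hit interval).
#' @export
repeat_density <- function(hits, genome_len) {
  if (genome_len <= 0) stop("genome_len must be positive")
  n_hits <- nrow(hits)
  if (n_hits == 0) {
    return(list(count_density = 0, bp_fraction = 0))
  }
  ivs <- if (!is.null(hits$start_b)) {
    rbind(data.frame(start = hits$start_a, len = hits$length),
          data.frame(start = hits$start_b, len = hits$length))
  } else {
    data.frame(start = hits$start, len = hits$total)
  }
  covered <- logical(genome_len)
  for (i in seq_len(nrow(ivs))) {
    idx <- (seq(ivs$start[i], length.out = min(ivs$len[i], genome_len)) %%
              genome_len) + 1L
    covered[idx] <- TRUE
  }
  list(count_density = n_hits * 1000 / genome_len,
       bp_fraction = mean(covered))
}
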