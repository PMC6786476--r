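## Large inverted repeat (IR) detection: self-similarity candidates from the
## assembly sequence, validated by read coverage and by read pairs that
## anchor in the IR on one end and in a single-copy region on the other.
## The acceptance rule formalizes what plastome studies do by eye on read
## stacks: a candidate passes when every IR/single-copy junction is
## supported by a minimum number of straddling pairs, or (for assemblies in
## which one IR copy was collapsed) when the interval's depth is about twice
## that of its flanks.

#' Find large inverted-repeat candidates
#'
#' Maximal inverted (reverse-complement) self-matches of the circular
#' assembly sequence, sorted by length descending. This is IR calling, not
#' the general repeat census: `min_len` below 50 bp is rejected.
#'
#' @param x a [plastome] or DNA string.
#' @param min_len minimum candidate length (default 1000 bp, separating
#'   large-IR calls from ordinary inverted repeats).
#' @param max_mismatch maximum substitutions between the two copies
#'   (default 0: plastome IR copies are near-identical).
#' @return data frame of candidates: `start_a`, `start_b` (0-based),
#'   `length`, `mismatches`.
#' @export
find_inverted_candidates <- function(x, min_len = 1000L, max_mismatch = 0L) {
  if (min_len < 50) stop("min_len < 50 bp: use find_maximal_repeats()")
  seq <- if (inherits(x, "plastome")) x$sequence else x
  n <- nchar(seq)
  seed_len <- min(31L, max(2L, as.integer(min_len) %/% (max_mismatch + 1L)))
  w <- .find_repeat_windows_cpp(seq, dna_revcomp(seq), as.integer(min_len),
                                as.integer(max_mismatch),
                                as.integer(seed_len))
  if (nrow(w) == 0) {
    return(data.frame(start_a = integer(), start_b = integer(),
                      length = integer(), mismatches = integer()))
  }
  start_a <- w[, "start_a"]
  start_b <- map_t_interval(w[, "start_t"], w[, "length"], n, "inverted")
  df <- data.frame(start_a = pmin(start_a, start_b),
                   start_b = pmax(start_a, start_b),
                   length = w[, "length"], mismatches = w[, "mismatches"])
  df <- df[df$start_a != df$start_b, , drop = FALSE]
  df <- df[!duplicated(df[, c("start_a", "start_b", "length")]), , drop = FALSE]
  if (nrow(df) > 0) {
    ov <- mapply(arc_intersect_len, df$start_a, df$length, df$start_b,
                 df$length, MoreArgs = list(n = n))
    df <- df[ov == 0, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[order(-df$length), , drop = FALSE]
}

candidate_intervals <- function(cand) {
  list(ira = c(cand$start_a, cand$start_a + cand$length),
       irb = c(cand$start_b, cand$start_b + cand$length))
}

read_fully_in <- function(pos, len, iv, n) {
  rel <- (pos - iv[1]) %% n
  rel + len <= (iv[2] - iv[1])
}

#' Split read-pair evidence for an IR candidate
#'
#' Reports two signals. `n_split_pairs` counts discordant pairs with one
#' mate inside an IR copy and the other anchored in single-copy sequence,
#' where the placement geometry is incompatible with the fragment model
#' (mates on the same strand, or an implied span far beyond the insert
#' size): these arise because a read from one IR copy is placed at the
#' other, so its single-copy mate appears stranded — the read-pair-split
#' signature of a real duplication, absent for any interval of a
#' single-copy genome. `junction_support` counts, for each of the four
#' IR/single-copy junctions, the pairs whose single-copy mate lies within
#' one insert length of the junction while the partner mate lies inside
#' the IR.
#'
#' @param placements paired placements from [map_reads()] (both mates per
#'   `qname` required).
#' @param candidate one row of [find_inverted_candidates()] output (as list
#'   or data frame row).
#' @param genome_len genome length (bp).
#' @param insert_mean fragment-length scale defining the junction windows.
#' @return list: `n_split_pairs`, `junction_support` (named length-4
#'   vector: `ira_left`, `ira_right`, `irb_left`, `irb_right`).
#' @export
split_pair_evidence <- function(placements, candidate, genome_len,
                                insert_mean = 650) {
  pl <- placements[isTRUE_vec(placements$mapped), , drop = FALSE]
  m1 <- pl[pl$mate == 1L, ]; m2 <- pl[pl$mate == 2L, ]
  common <- intersect(m1$qname, m2$qname)
  if (length(unique(placements$qname)) == 0 ||
      any(!table(placements$qname) %in% c(2L))) {
    stop("unpaired input: both mates required per qname")
  }
  i1 <- match(common, m1$qname); i2 <- match(common, m2$qname)
  p1 <- m1$pos[i1]; l1 <- m1$len[i1]
  p2 <- m2$pos[i2]; l2 <- m2$len[i2]
  s1 <- m1$strand[i1]; s2 <- m2$strand[i2]
  ivs <- candidate_intervals(as.list(candidate))
  n <- genome_len
  in_ir1 <- read_fully_in(p1, l1, ivs$ira, n) | read_fully_in(p1, l1, ivs$irb, n)
  in_ir2 <- read_fully_in(p2, l2, ivs$ira, n) | read_fully_in(p2, l2, ivs$irb, n)
  split <- xor(in_ir1, in_ir2)
  ## discordance: same-strand mates or an implied span incompatible with
  ## the fragment length distribution
  circ_span <- pmin((p1 - p2) %% n, (p2 - p1) %% n) + pmax(l1, l2)
  discordant <- (s1 == s2) | (circ_span > 2 * insert_mean)
  n_split <- sum(split & discordant)
  ## per-junction support: SC mate within `insert_mean` of the junction,
  ## on the single-copy side; partner mate inside the IR
  sc_pos <- ifelse(in_ir1, p2, p1)
  sc_len <- ifelse(in_ir1, l2, l1)
  sc_pos <- sc_pos[split]; sc_len <- sc_len[split]
  w <- insert_mean
  near <- function(iv, side) {
    if (side == "left") {
      win <- c((iv[1] - w) %% n, (iv[1] - w) %% n + w)
    } else {
      win <- c(iv[2] %% n, iv[2] %% n + w)
    }
    sum(read_fully_in(sc_pos, sc_len, win, n))
  }
  support <- c(ira_left = near(ivs$ira, "left"),
               ira_right = near(ivs$ira, "right"),
               irb_left = near(ivs$irb, "left"),
               irb_right = near(ivs$irb, "right"))
  list(n_split_pairs = n_split, junction_support = support)
}

#' Coverage-ratio test interval vs. flanks
#'
#' @param profile a `coverage_profile`.
#' @param interval `c(start, end)` 0-based half-open.
#' @param flank flank width (bp) on each side.
#' @return ratio of mean depth inside the interval to mean depth of the two
#'   flanks.
#' @export
coverage_ratio <- function(profile, interval, flank = 2000L) {
  n <- profile$genome_len
  inside <- interval_mean_depth(profile, interval)
  left <- interval_mean_depth(profile, c((interval[1] - flank) %% n,
                                         (interval[1] - flank) %% n + flank))
  right <- interval_mean_depth(profile, c(interval[2] %% n,
                                          interval[2] %% n + flank))
  fl <- mean(c(left, right))
  if (fl <= 0) return(Inf)
  inside / fl
}

#' Accept or reject IR candidates
#'
#' A candidate is accepted iff its length reaches `min_ir_len` and either
#' all four IR/single-copy junctions have at least `min_pairs` supporting
#' split pairs, or the interval/flank coverage ratio falls within
#' `cov_ratio_window` (the collapsed-assembly signature). Boundaries are
#' the outermost bases of the maximal sequence match, which read evidence
#' validates but never extends.
#'
#' @param candidates data frame from [find_inverted_candidates()].
#' @param coverage optional `coverage_profile`.
#' @param splits optional list of [split_pair_evidence()] results, one per
#'   candidate row.
#' @param genome_len genome length (bp).
#' @param min_ir_len minimum accepted IR length (default 1000).
#' @param min_pairs minimum split pairs per junction (default 5).
#' @param cov_ratio_window acceptance window for the coverage ratio
#'   (default `c(1.7, 2.3)`).
#' @return `NULL` when nothing passes, else a list of class `ir_call` with
#'   `ira`, `irb` intervals, `length`, and the supporting evidence.
#' @export
call_ir <- function(candidates, coverage = NULL, splits = NULL, genome_len,
                    min_ir_len = 1000L, min_pairs = 5L,
                    cov_ratio_window = c(1.7, 2.3)) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  ord <- order(-candidates$length)
  for (i in ord) {
    cand <- candidates[i, ]
    if (cand$length < min_ir_len) next
    ivs <- candidate_intervals(as.list(cand))
    ok_pairs <- FALSE; ok_cov <- FALSE
    support <- NULL; ratio <- NA_real_
    if (!is.null(splits)) {
      support <- splits[[i]]$junction_support
      ok_pairs <- all(support >= min_pairs)
    }
    if (!is.null(coverage)) {
      ratio <- coverage_ratio(coverage, ivs$ira)
      ok_cov <- ratio >= cov_ratio_window[1] && ratio <= cov_ratio_window[2]
    }
    if (ok_pairs || ok_cov) {
      return(structure(list(ira = ivs$ira, irb = ivs$irb,
                            length = cand$length,
                            mismatches = cand$mismatches,
                            junction_support = support,
                            coverage_ratio = ratio,
                            accepted_by = if (ok_pairs) "split_pairs"
                                          else "coverage_ratio"),
                       class = "ir_call"))
    }
  }
  NULL
}

#' @export
print.ir_call <- function(x, ...) {
  cat(sprintf("ir_call: %s bp IR, copies at [%d,%d) / [%d,%d), accepted by %s\n",
              format(x$length, big.mark = ","), x$ira[1], x$ira[2],
              x$irb[1], x$irb[2], x$accepted_by))
  invisible(x)
}

#' One-shot IR detection from an assembly and its reads
#'
#' Runs candidate finding, read mapping, coverage profiling, split-pair
#' evidence and the acceptance rule.
#'
#' @param genome a [plastome].
#' @param reads optional `read_set` for validation; without reads, only
#'   candidates with a passing coverage/split rule can be accepted, so the
#'   call returns the candidate list alongside a `NULL` call.
#' @param min_ir_len,max_mismatch,min_pairs,cov_ratio_window see
#'   [call_ir()] and [find_inverted_candidates()].
#' @return list with `candidates`, `call` (an `ir_call` or `NULL`),
#'   `coverage`, `placements`.
#' @export
detect_ir <- function(genome, reads = NULL, min_ir_len = 1000L,
                      max_mismatch = 0L, min_pairs = 5L,
                      cov_ratio_window = c(1.7, 2.3)) {
  cands <- find_inverted_candidates(genome, min_len = min_ir_len,
                                    max_mismatch = max_mismatch)
  n <- genome_length(genome)
  placements <- NULL; cov <- NULL; splits <- NULL
  if (!is.null(reads) && nrow(reads$pairs) > 0 && nrow(cands) > 0) {
    placements <- map_reads(reads, genome)
    cov <- coverage_profile(placements, n)
    splits <- lapply(seq_len(nrow(cands)), function(i)
      split_pair_evidence(placements, cands[i, ], n,
                          insert_mean = reads$insert_mean %||% 650))
  }
  call <- call_ir(cands, coverage = cov, splits = splits, genome_len = n,
                  min_ir_len = min_ir_len, min_pairs = min_pairs,
                  cov_ratio_window = cov_ratio_window)
  list(candidates = cands, call = call, coverage = cov,
       placements = placements)
}
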