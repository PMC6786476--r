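## Paired-end read simulation and a minimal seed-anchored read mapper.
## Reads are 150-bp pairs from ~650-bp fragments sampled uniformly on the
## circle; sequencing errors are uniform substitutions. The mapper places
## reads by exact 31-mer seed anchoring (several seed offsets per read, both
## strands) with ties broken by leftmost position — sufficient for simulated
## data, and replaceable by an external SAM subset (see read_sam_subset).

new_read_set <- function(pairs, read_len, insert_mean, insert_sd,
                         error_rate, seed, genome_len = NA_integer_) {
  structure(list(pairs = pairs, read_len = read_len,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, seed = seed,
                 genome_len = genome_len),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d pairs, read length %s bp\n",
              nrow(x$pairs), format(x$read_len)))
  invisible(x)
}

#' @export
length.read_set <- function(x) nrow(x$pairs)

#' Combine read sets
#' @param ... `read_set` objects with equal read lengths.
#' @return a `read_set` containing all pairs.
#' @export
merge_read_sets <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, function(s) nrow(s$pairs) > 0, logical(1))]
  if (length(sets) == 0) stop("no non-empty read sets")
  rl <- unique(vapply(sets, `[[`, numeric(1), "read_len"))
  stopifnot(length(rl) == 1)
  new_read_set(do.call(rbind, lapply(sets, `[[`, "pairs")),
               read_len = rl, insert_mean = sets[[1]]$insert_mean,
               insert_sd = sets[[1]]$insert_sd,
               error_rate = sets[[1]]$error_rate, seed = sets[[1]]$seed,
               genome_len = sets[[1]]$genome_len)
}

apply_seq_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    ch <- strsplit(seqs[i], "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate paired-end reads from a plastome
#'
#' Fragments of Gaussian length (truncated below at the read length) are
#' sampled uniformly on the circle, from either strand; each yields a mate
#' pair read inward from the fragment ends. The number of pairs is
#' `round(coverage * genome_len / (2 * read_len))`.
#'
#' @param x a [plastome] or DNA string.
#' @param coverage target mean depth.
#' @param read_len read length in bp (default 150).
#' @param insert_mean,insert_sd fragment-length distribution (default
#'   650 +/- 65 bp).
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @param circular sample fragments across the origin (default: the
#'   plastome's circularity flag).
#' @param qname_prefix prefix for read names.
#' @return a `read_set`; `pairs` records the true fragment origin of each
#'   pair (`frag_start`, `frag_len`, `strand`).
#' @export
simulate_reads <- function(x, coverage, read_len = 150L, insert_mean = 650,
                           insert_sd = 65, error_rate = 0, seed = 1,
                           circular = NULL, qname_prefix = "read") {
  seq <- if (inherits(x, "plastome")) x$sequence else x
  circular <- circular %||% (if (inherits(x, "plastome")) x$circular else TRUE)
  if (read_len > insert_mean) stop("read_len exceeds insert_mean")
  stopifnot(coverage >= 0)
  L <- nchar(seq)
  n_pairs <- round(coverage * L / (2 * read_len))
  if (n_pairs == 0) {
    return(new_read_set(
      data.frame(qname = character(), mate1 = character(),
                 mate2 = character(), frag_start = integer(),
                 frag_len = integer(), strand = character(),
                 stringsAsFactors = FALSE),
      read_len, insert_mean, insert_sd, error_rate, seed, L))
  }
  with_seed(seed, {
    frag_len <- pmax(read_len,
                     pmin(L, round(stats::rnorm(n_pairs, insert_mean, insert_sd))))
    if (circular) {
      frag_start <- sample.int(L, n_pairs, replace = TRUE) - 1L
    } else {
      frag_start <- vapply(frag_len, function(fl)
        sample.int(L - fl + 1L, 1L) - 1L, integer(1))
    }
    strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
    doubled <- paste0(seq, seq)
    frags <- substring(doubled, frag_start + 1L, frag_start + frag_len)
    neg <- strand == "-"
    frags[neg] <- dna_revcomp(frags[neg])
    mate1 <- substr(frags, 1L, read_len)
    mate2 <- dna_revcomp(substring(frags, frag_len - read_len + 1L, frag_len))
    mate1 <- apply_seq_errors(mate1, error_rate)
    mate2 <- apply_seq_errors(mate2, error_rate)
    new_read_set(
      data.frame(qname = sprintf("%s_%06d", qname_prefix, seq_len(n_pairs)),
                 mate1 = mate1, mate2 = mate2, frag_start = frag_start,
                 frag_len = frag_len, strand = strand,
                 stringsAsFactors = FALSE),
      read_len, insert_mean, insert_sd, error_rate, seed, L)
  })
}

#' Simulate low-depth insert fragments of a gene
#'
#' Emulates nuclear/mitochondrial copies of a deleted plastid gene: reads
#' are drawn only from a contiguous window covering `fraction` of the gene,
#' at `relative_depth` times the main plastome coverage.
#'
#' @param reference result of [make_reference_plastome()] or a [plastome]
#'   carrying the gene.
#' @param gene gene name.
#' @param fraction fraction of the gene retained (0 < fraction <= 1).
#' @param relative_depth depth of the fragment relative to `main_coverage`.
#' @param main_coverage main plastome mean depth.
#' @param read_len,error_rate,seed as in [simulate_reads()].
#' @return a `read_set` (possibly empty); attribute `window` records the
#'   retained `c(start, end)` interval in gene coordinates.
#' @export
simulate_insert_fragments <- function(reference, gene, fraction = 0.5,
                                      relative_depth = 0.3,
                                      main_coverage = 100, read_len = 150L,
                                      error_rate = 0, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1, relative_depth >= 0,
            main_coverage > 0)
  g <- if (inherits(reference, "plastome")) reference else reference$genome
  cds <- feature_seq(g, gene)
  glen <- nchar(cds)
  win_len <- max(read_len, floor(fraction * glen))
  win_len <- min(win_len, glen)
  with_seed(seed, {
    win_start <- sample.int(glen - win_len + 1L, 1L) - 1L
    window <- substr(cds, win_start + 1L, win_start + win_len)
    rs <- simulate_reads(window, coverage = relative_depth * main_coverage,
                         read_len = read_len,
                         insert_mean = max(read_len, min(650, win_len)),
                         insert_sd = min(65, max(1, win_len %/% 10)),
                         error_rate = error_rate,
                         seed = child_seed(seed, paste0("frag_", gene)),
                         circular = FALSE,
                         qname_prefix = paste0("frag_", gene))
    attr(rs, "window") <- c(win_start, win_start + win_len)
    rs
  })
}

## ---- minimal mapper ------------------------------------------------------

#' Build an exact k-mer position index over a sequence
#'
#' The index hashes every k-mer of the subject (wrapping the origin for
#' circular sequences) and supports batch position lookups; it is built
#' once per target and reused by the read mapper and the gene locator.
#'
#' @param x a [plastome] or DNA string.
#' @param k k-mer length (1-31).
#' @param circular index k-mers across the origin.
#' @return object of class `seed_index`.
#' @export
seed_index <- function(x, k = 31L, circular = TRUE) {
  seq <- if (inherits(x, "plastome")) x$sequence else x
  structure(list(ptr = .kmer_index_build_cpp(seq, as.integer(k),
                                             isTRUE(circular)),
                 k = as.integer(k), n = nchar(seq), circular = circular),
            class = "seed_index")
}

## leftmost 0-based hit per query (NA when absent)
seed_lookup_first <- function(index, queries) {
  hits <- .kmer_index_lookup_cpp(index$ptr, queries)
  vapply(hits, function(v) if (length(v)) min(v) else NA_integer_,
         integer(1))
}

#' Place reads on a genome by exact-seed anchoring
#'
#' Exact seeds (default 31-mers) at up to three offsets per read are looked
#' up in a k-mer index of the target on both strands; each read is placed
#' at the leftmost compatible position (ties to the leftmost, forward
#' strand preferred). Reads whose seeds all carry errors stay unmapped.
#'
#' @param reads a `read_set`.
#' @param genome a [plastome] or DNA string.
#' @param circular treat the target as circular.
#' @param seed_len seed length (default 31).
#' @param index optional prebuilt [seed_index()] for the target.
#' @return data frame of placements: `qname`, `mate`, `pos` (0-based),
#'   `strand`, `len`, `mapped`.
#' @export
map_reads <- function(reads, genome, circular = NULL, seed_len = 31L,
                      index = NULL) {
  seq <- if (inherits(genome, "plastome")) genome$sequence else genome
  circular <- circular %||%
    (if (inherits(genome, "plastome")) genome$circular else TRUE)
  L <- nchar(seq)
  p <- reads$pairs
  all_seqs <- c(p$mate1, p$mate2)
  qname <- c(p$qname, p$qname)
  mate <- rep(c(1L, 2L), each = nrow(p))
  if (length(all_seqs) == 0) {
    return(data.frame(qname = character(), mate = integer(), pos = integer(),
                      strand = character(), len = integer(),
                      mapped = logical(), stringsAsFactors = FALSE))
  }
  if (is.null(index)) index <- seed_index(seq, seed_len, circular)
  stopifnot(index$k == seed_len)
  len <- nchar(all_seqs)
  m <- length(all_seqs)
  rl <- max(len)
  offsets <- unique(pmax(0L, c(0L, as.integer(rl %/% 2) - seed_len %/% 2L,
                               rl - seed_len)))
  best_f <- rep(NA_integer_, m)
  best_r <- rep(NA_integer_, m)
  for (o in offsets) {
    sel <- which(len >= o + seed_len)
    if (length(sel) == 0) next
    sf <- substring(all_seqs[sel], o + 1L, o + seed_len)
    pf <- seed_lookup_first(index, sf) - o
    upd <- !is.na(pf) & (is.na(best_f[sel]) | pf < best_f[sel])
    best_f[sel[upd]] <- pf[upd]
    ## minus strand: seed at offset o of the reverse-complemented read
    sr <- dna_revcomp(substring(all_seqs[sel], len[sel] - o - seed_len + 1L,
                                len[sel] - o))
    pr <- seed_lookup_first(index, sr) - o
    upd <- !is.na(pr) & (is.na(best_r[sel]) | pr < best_r[sel])
    best_r[sel[upd]] <- pr[upd]
  }
  use_f <- !is.na(best_f) & (is.na(best_r) | best_f <= best_r)
  pos <- ifelse(use_f, best_f, best_r)
  strand <- ifelse(use_f, "+", "-")
  mapped <- !is.na(pos)
  if (!circular) {
    bad <- mapped & (pos < 0L | pos + len > L)
    pos[bad] <- NA_integer_
    mapped[bad] <- FALSE
  }
  pos0 <- ifelse(mapped, pos %% L, NA_integer_)
  data.frame(qname = qname, mate = mate, pos = as.integer(pos0),
             strand = ifelse(mapped, strand, NA_character_),
             len = len, mapped = mapped, stringsAsFactors = FALSE)
}

#' Per-base read depth along a genome
#'
#' @param placements placement data frame from [map_reads()] or
#'   [read_sam_subset()].
#' @param genome_len genome length in bp.
#' @param circular wrap read footprints across the origin.
#' @return object of class `coverage_profile`: list with `depth` (numeric
#'   vector of length `genome_len`) and `genome_len`.
#' @export
coverage_profile <- function(placements, genome_len, circular = TRUE) {
  stopifnot(genome_len > 0)
  pl <- placements[isTRUE_vec(placements$mapped), , drop = FALSE]
  if (nrow(pl) > 0) {
    if (any(pl$pos < 0 | pl$pos >= genome_len)) {
      stop("placement position out of range")
    }
    if (!circular && any(pl$pos + pl$len > genome_len)) {
      stop("placement extends past the end of a linear genome")
    }
  }
  delta <- numeric(genome_len + 1L)
  if (nrow(pl) > 0) {
    s <- pl$pos
    e <- pmin(pl$pos + pl$len, if (circular) Inf else genome_len)
    wrap <- e > genome_len
    ## non-wrapping part
    add <- function(st, en) {
      t1 <- tabulate(st + 1L, nbins = genome_len + 1L)
      t2 <- tabulate(en + 1L, nbins = genome_len + 1L)
      delta <<- delta + t1 - t2
    }
    add(s, pmin(e, genome_len))
    if (any(wrap)) add(rep(0L, sum(wrap)), e[wrap] - genome_len)
  }
  depth <- cumsum(delta[seq_len(genome_len)])
  structure(list(depth = depth, genome_len = genome_len),
            class = "coverage_profile")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Mean depth over a (possibly wrapped) interval
#' @param profile a `coverage_profile`.
#' @param interval `c(start, end)` 0-based half-open, wrap allowed.
#' @return mean depth.
#' @export
interval_mean_depth <- function(profile, interval) {
  n <- profile$genome_len
  idx <- (seq(interval[1], interval[2] - 1L) %% n) + 1L
  mean(profile$depth[idx])
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile: %d bp, mean depth %.1f (min %.0f, max %.0f)\n",
              x$genome_len, mean(x$depth), min(x$depth), max(x$depth)))
  invisible(x)
}

#' Read placements from a minimal SAM subset
#'
#' Accepts SAM lines using only QNAME, FLAG, RNAME, POS and M-only CIGAR
#' fields, as produced by external mappers, as an alternative to
#' [map_reads()].
#'
#' @param path SAM file path.
#' @return placement data frame as from [map_reads()].
#' @export
read_sam_subset <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(qname = character(), mate = integer(), pos = integer(),
                      strand = character(), len = integer(),
                      mapped = logical(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(parts, function(x) as.integer(x[2]), integer(1))
  cigar <- vapply(parts, function(x) x[6], character(1))
  ok <- grepl("^[0-9]+M$", cigar)
  mlen <- rep(NA_integer_, length(cigar))
  mlen[ok] <- as.integer(sub("M$", "", cigar[ok]))
  if (anyNA(mlen[!bitwAnd(flag, 4L)])) {
    stop("only M-only CIGARs are supported")
  }
  data.frame(
    qname = vapply(parts, `[[`, character(1), 1L),
    mate = ifelse(bitwAnd(flag, 64L) > 0, 1L, 2L),
    pos = vapply(parts, function(x) as.integer(x[4]), integer(1)) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0, "-", "+"),
    len = mlen,
    mapped = bitwAnd(flag, 4L) == 0L,
    stringsAsFactors = FALSE)
}
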